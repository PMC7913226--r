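# Assemble the embedded reference tables and freeze them as text fixtures.
# Run once from repo root: Rscript scratch/make_fixtures.R
out <- "inst/extdata"

organs <- c("bone","brain","fat","gonads","intestines","lung","stomach","heart",
            "kidney","liver","muscle","pancreas","skin","spleen",
            "blood_arterial","blood_venous","blood_portal")

# Organ masses (kg) at grid ages; fat closes the mass balance to target BWT.
# ICRP-style reference values; unisex through age 10.
mk <- function(bwt, ht, bone, brain, gonads, intestines, lung, stomach, heart,
               kidney, liver, muscle, pancreas, skin, spleen, blood) {
  art <- 0.2377 * blood; ven <- 0.6736 * blood; por <- blood - art - ven
  m <- c(bone = bone, brain = brain, fat = NA, gonads = gonads,
         intestines = intestines, lung = lung, stomach = stomach, heart = heart,
         kidney = kidney, liver = liver, muscle = muscle, pancreas = pancreas,
         skin = skin, spleen = spleen, blood_arterial = art,
         blood_venous = ven, blood_portal = por)
  m["fat"] <- bwt - sum(m, na.rm = TRUE)
  stopifnot(m["fat"] > 0)
  list(bwt = bwt, ht = ht, m = m)
}

grid <- list(
  `0.25` = mk(6.0,  61.0, 0.80, 0.64, 0.0008, 0.13, 0.060, 0.020, 0.035, 0.042, 0.23, 1.45, 0.010, 0.35, 0.018, 0.45),
  `1`    = mk(9.6,  75.7, 1.40, 0.95, 0.0010, 0.19, 0.090, 0.028, 0.050, 0.070, 0.33, 2.70, 0.015, 0.55, 0.026, 0.72),
  `2`    = mk(12.2, 87.1, 1.80, 1.12, 0.0012, 0.24, 0.105, 0.034, 0.060, 0.082, 0.40, 3.70, 0.020, 0.68, 0.033, 0.92),
  `3`    = mk(14.3, 96.1, 2.10, 1.23, 0.0014, 0.28, 0.120, 0.039, 0.070, 0.091, 0.46, 4.50, 0.026, 0.79, 0.039, 1.08),
  `4`    = mk(16.3, 103.3, 2.45, 1.29, 0.0016, 0.32, 0.140, 0.044, 0.080, 0.100, 0.52, 5.30, 0.031, 0.90, 0.046, 1.23),
  `5`    = mk(18.3, 110.0, 2.80, 1.32, 0.0018, 0.36, 0.155, 0.050, 0.090, 0.110, 0.58, 6.20, 0.036, 1.00, 0.052, 1.38),
  `10`   = mk(32.0, 138.0, 5.20, 1.40, 0.0030, 0.56, 0.260, 0.080, 0.145, 0.180, 0.93, 12.0, 0.060, 1.70, 0.085, 2.40)
)
grid_m <- c(grid, list(
  `15` = mk(56.0, 167.0, 9.00, 1.44, 0.022, 0.82, 0.40, 0.12, 0.25, 0.25, 1.45, 24.0, 0.11, 2.70, 0.125, 4.20),
  `30` = mk(73.0, 176.0, 10.5, 1.45, 0.035, 1.00, 0.50, 0.15, 0.33, 0.31, 1.80, 29.0, 0.14, 3.30, 0.150, 5.30),
  `80` = mk(73.0, 176.0, 10.5, 1.45, 0.035, 1.00, 0.50, 0.15, 0.33, 0.31, 1.80, 29.0, 0.14, 3.30, 0.150, 5.30)
))
grid_f <- c(grid, list(
  `15` = mk(53.0, 161.0, 7.80, 1.30, 0.010, 0.82, 0.36, 0.12, 0.22, 0.24, 1.30, 19.0, 0.10, 2.30, 0.120, 3.50),
  `30` = mk(60.0, 163.0, 7.80, 1.30, 0.011, 0.96, 0.42, 0.14, 0.25, 0.275, 1.40, 17.5, 0.12, 2.30, 0.130, 4.10),
  `80` = mk(60.0, 163.0, 7.80, 1.30, 0.011, 0.96, 0.42, 0.14, 0.25, 0.275, 1.40, 17.5, 0.12, 2.30, 0.130, 4.10)
))

# Specific perfusion, L/h per kg tissue; lung and blood pools carry none
# (the lung is in series and receives the whole cardiac output).
perf <- c(bone = 1.60, brain = 28.97, fat = 0.893, gonads = 4.86,
          intestines = 47.0, lung = 0, stomach = 22.7, heart = 40.6,
          kidney = 200.0, liver = 12.1, muscle = 1.97, pancreas = 24.3,
          skin = 5.15, spleen = 66.7, blood_arterial = 0, blood_venous = 0,
          blood_portal = 0)

hct <- c(`0.25` = 0.35, `1` = 0.36, `2` = 0.37, `3` = 0.375, `4` = 0.38,
         `5` = 0.38, `10` = 0.40, `15` = 0.44, `30` = 0.47, `80` = 0.47)
hct_f <- hct; hct_f[c("15","30","80")] <- c(0.40, 0.42, 0.42)
alb <- c(`0.25` = 38, `1` = 40, `2` = 41, `3` = 41.5, `4` = 42, `5` = 42,
         `10` = 42, `15` = 42.5, `30` = 42.5, `80` = 42.5)
alb_f <- alb; alb_f[c("30","80")] <- 42.0
agp <- c(`0.25` = 0.45, `1` = 0.55, `2` = 0.60, `3` = 0.65, `4` = 0.65,
         `5` = 0.70, `10` = 0.75, `15` = 0.80, `30` = 0.80, `80` = 0.80)

gfr_mat <- function(a) pmin(1, (a^2 / (a^2 + 0.3^2)) / (30^2 / (30^2 + 0.3^2)))
gfr_for <- function(bwt, age, adult_bwt, adult_gfr)
  adult_gfr * (bwt / adult_bwt)^0.75 * gfr_mat(age)

rows <- list(); srows <- list()
for (sex in c("male","female")) {
  g <- if (sex == "male") grid_m else grid_f
  h <- if (sex == "male") hct else hct_f
  ab <- if (sex == "male") alb else alb_f
  adult_gfr <- if (sex == "male") 7.2 else 6.5
  adult_bwt <- if (sex == "male") 73 else 60
  for (a in names(g)) {
    gi <- g[[a]]
    stopifnot(abs(sum(gi$m) - gi$bwt) < 1e-9)
    rows[[length(rows) + 1]] <- data.frame(
      age_y = as.numeric(a), sex = sex, compartment = names(gi$m),
      mass_kg = round(unname(gi$m), 6),
      perfusion_L_h_kg = unname(perf[names(gi$m)]))
    srows[[length(srows) + 1]] <- data.frame(
      age_y = as.numeric(a), sex = sex, bwt_kg = gi$bwt, ht_cm = gi$ht,
      hematocrit = unname(h[a]), albumin_g_L = unname(ab[a]),
      agp_g_L = unname(agp[a]),
      gfr_L_h = round(gfr_for(gi$bwt, as.numeric(a), adult_bwt, adult_gfr), 4))
  }
}
phys <- do.call(rbind, rows); scal <- do.call(rbind, srows)

# -- sanity: cardiac output reduction under the severe scaling set ----------
severe_factors <- c(bone = 0.869, brain = 0.797, fat = 0.624, gonads = 0.84,
            intestines = 0.84, lung = 0.84, stomach = 0.84, heart = 0.758,
            kidney = 0.686, liver = 0.682, muscle = 0.715, pancreas = 0.84,
            skin = 0.879, spleen = 0.612, blood_arterial = 0.833,
            blood_venous = 0.822, blood_portal = 0.825)
ref <- grid_m[["30"]]$m
target <- 73 * 0.739
scaled <- ref * severe_factors[names(ref)]
fm <- c("fat","muscle")
mult <- (target - sum(scaled[setdiff(names(ref), fm)])) / sum(scaled[fm])
scaled[fm] <- scaled[fm] * mult
co_ref <- sum(perf[names(ref)] * ref)
co_sev <- sum(perf[names(ref)] * scaled)
cat(sprintf("fat/muscle multiplier %.4f; severe BWT %.2f; CO reduction %.1f%%\n",
            mult, sum(scaled), 100 * (1 - co_sev / co_ref)))
stopifnot(abs(sum(scaled) - target) < 1e-9,
          abs(100 * (1 - co_sev / co_ref) - 23) < 3)

dir.create(out, recursive = TRUE, showWarnings = FALSE)
write.csv(phys, file.path(out, "reference_physiology.csv"), row.names = FALSE, quote = FALSE)
write.csv(scal, file.path(out, "reference_scalars.csv"), row.names = FALSE, quote = FALSE)

# -- growth reference (WHO-standards-like medians; SD = 8% of median) -------
wfh_b <- c(`65` = 7.4, `70` = 8.4, `75` = 9.3, `80` = 10.4, `85` = 11.7,
           `90` = 12.9, `95` = 14.1, `100` = 15.4, `105` = 16.8, `110` = 18.4,
           `115` = 20.3, `120` = 22.4, `125` = 24.7)
wfh_g <- c(`65` = 7.2, `70` = 8.2, `75` = 9.1, `80` = 10.2, `85` = 11.5,
           `90` = 12.7, `95` = 13.9, `100` = 15.2, `105` = 16.8, `110` = 18.6,
           `115` = 20.7, `120` = 23.0, `125` = 25.4)
gr <- rbind(
  data.frame(sex = "male", height_cm = as.numeric(names(wfh_b)),
             median_kg = unname(wfh_b), sd_kg = round(0.08 * unname(wfh_b), 3)),
  data.frame(sex = "female", height_cm = as.numeric(names(wfh_g)),
             median_kg = unname(wfh_g), sd_kg = round(0.08 * unname(wfh_g), 3)))
write.csv(gr, file.path(out, "growth_reference_wfh.csv"), row.names = FALSE, quote = FALSE)

wfa_b <- data.frame(age_months = c(3, 6, 12, 24, 36, 48, 60),
                    median_kg = c(6.4, 7.9, 9.6, 12.2, 14.3, 16.3, 18.3))
wfa_g <- data.frame(age_months = c(3, 6, 12, 24, 36, 48, 60),
                    median_kg = c(5.8, 7.3, 8.9, 11.5, 13.9, 16.1, 18.2))
wfa <- rbind(cbind(sex = "male", wfa_b), cbind(sex = "female", wfa_g))
wfa$sd_kg <- round(0.11 * wfa$median_kg, 3)
write.csv(wfa, file.path(out, "growth_reference_wfa.csv"), row.names = FALSE, quote = FALSE)
cat("fixtures written\n")
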
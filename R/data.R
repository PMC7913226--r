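#' @useDynLib malnpbpk
#' @importFrom stats approx coef lm median quantile rlnorm rnorm runif sd setNames
#' @importFrom utils read.csv
NULL

# Package-level cache for the embedded reference tables.
.maln <- new.env(parent = emptyenv())

.extdata <- function(...) {
  p <- system.file("extdata", ..., package = "malnpbpk")
  if (!nzchar(p)) stop("missing packaged data file: ", file.path(...))
  p
}

.cached_csv <- function(key, file) {
  if (is.null(.maln[[key]])) {
    .maln[[key]] <- read.csv(.extdata(file), stringsAsFactors = FALSE)
  }
  .maln[[key]]
}

#' Compartment names of the whole-body model
#'
#' The 14 perfused organs/tissues plus the three circulating blood pools,
#' in the canonical order used throughout the package.
#' @param blood include the blood pools (default TRUE)
#' @return character vector of compartment names
#' @export
compartment_names <- function(blood = TRUE) {
  org <- c("bone", "brain", "fat", "gonads", "intestines", "lung", "stomach",
           "heart", "kidney", "liver", "muscle", "pancreas", "skin", "spleen")
  if (blood) c(org, "blood_arterial", "blood_venous", "blood_portal") else org
}

reference_physiology_table <- function() {
  .cached_csv("phys", "reference_physiology.csv")
}

reference_scalars_table <- function() {
  .cached_csv("scal", "reference_scalars.csv")
}

tissue_composition_table <- function() {
  .cached_csv("tissue", "tissue_composition.csv")
}

gi_segment_table <- function() {
  .cached_csv("gi", "gi_segments.csv")
}

reference_study_table <- function() {
  .cached_csv("t1", "reference_study_measurements.csv")
}

psp_fixture_table <- function() {
  .cached_csv("t2", "psp_table.csv")
}

# Map model compartments onto tissue-composition rows.
.tissue_for_compartment <- c(
  bone = "bone", brain = "brain", fat = "adipose", gonads = "gonads",
  intestines = "gut", lung = "lung", stomach = "gut", heart = "heart",
  kidney = "kidney", liver = "liver", muscle = "muscle",
  pancreas = "pancreas", skin = "skin", spleen = "spleen")

#' Tissue composition for a model compartment
#'
#' Volume/weight fractions (water, neutral lipid, neutral phospholipid,
#' protein), acidic-phospholipid content and tissue:plasma albumin ratio
#' used by the partition-coefficient methods.
#' @param compartment one of `compartment_names(blood = FALSE)`, or
#'   `"plasma"` / `"rbc"`
#' @return one-row data.frame of composition fields
#' @export
tissue_composition <- function(compartment) {
  tab <- tissue_composition_table()
  key <- if (compartment %in% c("plasma", "rbc")) compartment
         else .tissue_for_compartment[[compartment]]
  row <- tab[tab$tissue == key, , drop = FALSE]
  if (nrow(row) != 1L) stop("no tissue composition for ", compartment)
  row
}
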
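caffeine:
  development:
    route: oral_solution
    dose_mg: 300.0
    prandial: fasted
    age_range_y: [20.0, 40.0]
    sim_hours: 48.0
    matrix: plasma
  pediatric:
    route: oral_solution
    dose_mg: 40.0
    dose_mg_kg: 3.2
    prandial: fed
    meal: {volume_mL: 100.0, kcal: 75.0}
    age_range_y: [1.3, 4.5]
    sim_hours: 48.0
    matrix: plasma
cefoxitin:
  development:
    route: iv_infusion
    dose_mg: 2000.0
    infusion_min: 5.0
    age_range_y: [20.0, 40.0]
    sim_hours: 12.0
    matrix: plasma
  pediatric:
    route: iv_infusion
    dose_mg: 520.0
    dose_mg_kg: 40.0
    infusion_min: 5.0
    age_range_y: [1.333, 3.333]
    sim_hours: 24.0
    matrix: plasma
ciprofloxacin:
  development:
    route: oral_suspension
    particle_radius_um: 10.0
    dose_mg: 750.0
    prandial: fasted
    age_range_y: [20.0, 40.0]
    sim_hours: 48.0
    matrix: plasma
  pediatric:
    route: oral_suspension
    particle_radius_um: 10.0
    dose_mg: 120.0
    dose_mg_kg: 10.0
    prandial: fed
    meal: {volume_mL: 200.0, kcal: 300.0}
    age_range_y: [1.8, 2.2]
    sim_hours: 48.0
    matrix: plasma
lumefantrine:
  development:
    route: oral_solid
    dose_mg: 480.0
    prandial: fed
    age_range_y: [20.0, 40.0]
    sim_hours: 480.0
    matrix: plasma
  pediatric:
    route: oral_solid
    dose_mg: 120.0
    dose_mg_kg: 12.0
    prandial: fed
    meal: {volume_mL: 100.0, kcal: 75.0}
    age_range_y: [0.5, 5.0]
    sim_hours: 480.0
    matrix: plasma
pyrimethamine:
  development:
    route: oral_solid
    dose_mg: 25.0
    prandial: fasted
    age_range_y: [20.0, 40.0]
    sim_hours: 960.0
    matrix: blood
  pediatric:
    route: oral_solid
    dose_mg: 25.0
    dose_mg_kg: 1.8
    prandial: fasted
    age_range_y: [0.5, 5.0]
    sim_hours: 960.0
    matrix: blood
sulfadoxine:
  development:
    route: oral_solid
    dose_mg: 500.0
    prandial: fasted
    age_range_y: [20.0, 40.0]
    sim_hours: 2400.0
    matrix: blood
  pediatric:
    route: oral_solid
    dose_mg: 500.0
    dose_mg_kg: 36.0
    prandial: fasted
    age_range_y: [0.5, 5.0]
    sim_hours: 2400.0
    matrix: blood
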
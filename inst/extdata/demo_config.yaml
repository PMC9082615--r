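# Demonstration pipeline: synthetic mid-sized surfactant (propanol-like
# adsorption strength) on a mildly hydrophobic surface.
seed: 42
constants:
  T: 300
  gamma0: 57.8      # water-vapor tension of the emulated water model, mN/m
  theta_deg: 97     # neat contact angle of the solid surface
generate:
  slab:
    box_height: 10
    slab_center: 5
    slab_thickness: 5
    interface_width: 0.25
    bulk_water_density: 33.3
  truth:
    c0_mol_l: 0.1
    gamma_true: 1.0
    peak_width: 0.3
  isotherm_v:
    k_c: 4.15          # nm^3  (K_v = k_c * gamma_inf ~ 21 nm)
    gamma_inf: 5.06    # nm^-2
    concentrations: [0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.8]
    noise_x: 0.05
    noise_y: 0.05
  isotherm_s:
    k_c: 1.7           # nm^3  (K_s ~ 8.6 nm at theta = 97 deg)
    gamma_inf: 5.06
    concentrations: [0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.8]
    noise_x: 0.05
    noise_y: 0.05
  rdf:
    mm:
      form: exp_decay
      amplitude: -0.9
      decay_length: 0.3
      r_max: 3
    mw:
      form: exp_decay
      amplitude: -0.5
      decay_length: 0.25
      r_max: 3
fit:
  weighting: auto
droplet:
  c0_grid: [0.0, 0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5]
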
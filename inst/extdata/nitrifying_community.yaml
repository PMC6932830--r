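domain:
  lengths:
  - 0.0001
  - 0.0001
  - 0.0001
  voxel: 1.0e-05
  periodic:
  - yes
  - yes
  - no
  boundary_layer: 2.0e-05
groups:
  HET:
    density: 150.0
    division_diameter: 1.3e-06
    death_diameter: 4.0e-07
    decay_rate: 4.63e-06
    yield: 0.61
    eps:
      density: 30.0
      yield: 0.18
      shell_ratio: 1.25
    pathways:
      aerobic:
        mumax: 6.940000000000001e-05
        eta: 1.0
        K:
          sub: 0.004
          o2: 0.0002
        stoich:
          sub: -1.639344262295082
          o2: -0.344262295081967
      anoxic_no3:
        mumax: 6.940000000000001e-05
        eta: 0.6
        K:
          sub: 0.004
          no3: 0.0005
        inhibition:
          o2: 0.0002
        stoich:
          sub: -1.639344262295082
          no3: -0.120371431846842
      anoxic_no2:
        mumax: 6.940000000000001e-05
        eta: 0.6
        K:
          sub: 0.004
          no2: 0.0003
        inhibition:
          o2: 0.0002
        stoich:
          sub: -1.639344262295082
          no2: -0.201322979580098
    active: yes
    lysis_rate: 0.0
  AOB:
    density: 150.0
    division_diameter: 1.3e-06
    death_diameter: 4.0e-07
    decay_rate: 1.27e-06
    yield: 0.33
    pathways:
      aerobic:
        mumax: 1.16e-05
        eta: 1.0
        K:
          nh4: 0.001
          o2: 0.0005
        stoich:
          nh4: -3.03030303030303
          o2: -9.363636363636363
          no2: 3.03030303030303
    active: yes
    lysis_rate: 0.0
  NOB:
    density: 150.0
    division_diameter: 1.3e-06
    death_diameter: 4.0e-07
    decay_rate: 6.94e-07
    yield: 0.083
    pathways:
      aerobic:
        mumax: 9.15e-06
        eta: 1.0
        K:
          no2: 0.0013
          o2: 0.00068
        stoich:
          no2: -12.048192771084336
          o2: -12.855421686746986
          no3: 12.048192771084336
    active: yes
    lysis_rate: 0.0
  EPS:
    density: 30.0
    active: no
    adhesive: yes
    death_diameter: 0.0
    division_diameter: .inf
    decay_rate: 0.0
    yield: 1.0
    lysis_rate: 0.0
  DEAD:
    density: 150.0
    active: no
    lysis_rate: 1.0e-06
    death_diameter: 4.0e-07
    division_diameter: .inf
    decay_rate: 0.0
    yield: 1.0
solutes:
  sub:
    diffusion: 1.6e-09
    bulk: 0.004
    influent: 0.004
    fixed_bulk: no
  o2:
    diffusion: 2.3e-09
    bulk: 0.01
    influent: 0.01
    fixed_bulk: yes
  nh4:
    diffusion: 1.8e-09
    bulk: 0.03
    influent: 0.03
    fixed_bulk: no
  no2:
    diffusion: 1.7e-09
    bulk: 0.0
    influent: 0.0
    fixed_bulk: no
  no3:
    diffusion: 1.7e-09
    bulk: 0.0
    influent: 0.0
    fixed_bulk: no
bulk:
  Q: 5.0e-11
  V: 1.0e-06
  A_f: 0.03
mechanics:
  Kn: 0.001
  gamma_n: 100000.0
  Ha: 9.999999999999999e-21
  h_floor: 1.0e-09
timesteps:
  bio: 900.0
  mechanical: 1.0e-07
  t_end: 9000.0
  diffusion: ~
solver:
  diffusion_tol: 1.0e-05
  relax_max_steps: 800
  relax_window: 50
  max_sweeps: 200000
  pressure_tol: 0.001
processes:
- mass_balance
- bulk
- growth
- division
- death
- eps
- lysis
- mechanics
seed: 1
output:
  every: 1
  dir: ~
  vtk: no
kinetics: monod
division_distance: radius_sum
lysis_solute: sub

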
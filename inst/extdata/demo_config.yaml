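calibration:
  pixel_size: 162.5
  frame_interval: 1
seed: 5
registration:
  chained: true
simulation:
  geometry:
    base_point: [800, 7800]
    tip_point: [14800, 7800]
  config:
    image_shape: [96, 96]
    n_frames: 40
    quantal_yield: 800
    drift:
      velocity: [2, -1]
      random_walk_sd: 3
  emitters:
    - {motility: {mode: processive, speed: 100}, start: 500}
    - {motility: {mode: diffusive, diffusion_coeff: 20000}, start: 7500}
    - {motility: {mode: static}, start: 6100}
    - {motility: {mode: static}, start: 11300}
    - {motility: {mode: static}, start: 12400}
    - {motility: {mode: static}, start: 13300}
    - {motility: {mode: static}, photophysics: {n_fluorophores: 18}, start: 5200}
    - {motility: {mode: static}, photophysics: {n_fluorophores: 20}, start: 10400}
    - {motility: {mode: static}, photophysics: {n_fluorophores: 15}, start: 13900}
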
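# Demo pipeline configuration: two fully synthetic conditions emulating a
# microgravity-vs-ground comparison. Every stage key shown here is optional;
# omitted values fall back to the defaults documented in ?run_pipeline.
seed: 1
conditions:
  space:
    saxs:
      noise: 0.02            # fractional intensity noise
      n_points: 300          # log-spaced Q grid on 0.07-2.5 nm^-1
      reference_condition: space   # truth parameters for the generator
    waxs:
      noise: 0.01
      areas: [125, 88.8, 93.9]     # 020 areas per position (upper/middle/bottom)
    maldi:
      mean_dp: 6.9
    ribbons:
      n_ribbons: 120
      pixel_size: 0.05       # um/px
      width_mean: 0.254      # um
      width_sd: 0.128
  ground:
    saxs:
      noise: 0.02
      n_points: 300
      reference_condition: ground
    waxs:
      noise: 0.01
      areas: [188, 234, 246]
    maldi:
      mean_dp: 6.35
    ribbons:
      n_ribbons: 120
      pixel_size: 0.05
      width_mean: 0.584
      width_sd: 0.370
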
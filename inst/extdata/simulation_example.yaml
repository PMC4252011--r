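# Arc-simulation configuration: a machine with typical clinical deformation
# amplitudes, acquired in integrated mode (10-degree steps, 37 images).
model:
  sdd0: 1500
  epidSagX: {sin1: 0.085}
  epidSagY: {cos1: -0.5}
  gantrySagX: {sin1: 0.21}
  gantrySagY: {cos1: -0.35}
  sddVariation: {cos1: -0.85}
  skew: {cos1: -0.075}
  tiltX: {sin1: 0.01}
  tiltY: {cos1: -0.05}
  carriageL: {sin1: -0.41}
  carriageR: {sin1: 0.34}
  carriageG: {cos1: -0.17}
  carriageT: {cos1: 0.16}
  eMarkerOffset: [0.8, -0.5]
  gaussianSd: 0.01
  saltFraction: 0.002
  seed: 1
plan:
  mode: integrated
  stepDeg: 10
  direction: CW
  collimator: 0
panel: aS1000
replicates: 1
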
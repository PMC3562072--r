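# Synthetic 5-basis Hardy multiquadric fitness model for the 5-gene
# reference benchmark network. Synthetic values: constructed for this
# package's benchmark, not taken from any measured system.
#
# Design (fixed once, at design time): the centres are scattered across the
# expression range [0, 2]^5 so the fitness surface is sensitive to every
# gene's expression level, and the coefficients solve the noise-free
# interpolation problem that assigns the five single-knockout strains the
# distinct positive fitness values 1.5, 2.0, 2.5, 1.2 and 1.0 (deletions of
# genes 1..5 respectively). Under these levels the correlation score ranks
# the hub gene (gene 3, out-degree 4) first, giving the feeding order
# 3, 2, 1, 4, 5.
n_bases: 5
shape_const: 0.5
obs_noise_var: 0.01
centres:
  - [1.98, 1.58, 0.34, 0.17, 1.28]
  - [0.80, 0.68, 0.46, 1.12, 0.59]
  - [0.23, 1.94, 1.55, 0.02, 1.99]
  - [0.14, 0.33, 0.19, 1.97, 1.81]
  - [0.49, 0.92, 0.91, 0.63, 1.98]
coefficients: [1.5085, -5.8906, -0.9675, 3.1668, 0.6394]
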
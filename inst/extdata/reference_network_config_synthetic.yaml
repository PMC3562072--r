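# Flat configuration for the 5-gene reference benchmark network: sigmoid
# steepness, expression biases and noise variances, plus the simulation
# protocol (rounds of knockout measurements, settling steps, initial level).
n_genes: 5
sigmoid_params: [1.0, 1.0, 1.0, 1.0, 1.0]
biases: [0.2, 0.2, 0.2, 0.2, 0.2]
process_noise_var: 0.01
rounds: 10
settle_steps: 20
init_level: 0.5
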
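# Language-acquisition protocol: a naive child learning from three fluent
# parents. Omitted keys take the protocol defaults (eta = 32, alpha = 32,
# 32 episodes of 16 epochs).
experiment: acquisition
seed: 7
eta: 32
n_episodes: 32
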
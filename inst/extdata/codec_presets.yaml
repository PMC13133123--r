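# Standardized codec parameter sets targeting code rates of 0.50, 1.00
# and 1.50 bit per nt at a design length of 150 nt (37 payload bytes per
# sequence plus 2 nt of pad).  The inner/outer redundancy split for the
# Reed-Solomon codec is a free design choice at each rate: more inner
# parity at lower rates (deeper per-sequence correction), with the
# remaining redundancy spent on outer erasure capacity.  Fountain
# presets spend almost all redundancy on droplet overhead, keeping only
# a 2-byte detection parity per droplet.
rs:
  rate_0.50: {L: 150, inner_parity: 10, outer_n: 100, outer_k: 36}
  rate_1.00: {L: 150, inner_parity: 6, outer_n: 100, outer_k: 62}
  rate_1.50: {L: 150, inner_parity: 4, outer_n: 100, outer_k: 87}
fountain:
  rate_0.50: {L: 150, epsilon: 2.52, parity_bytes: 2}
  rate_1.00: {L: 150, epsilon: 0.76, parity_bytes: 2}
  rate_1.50: {L: 150, epsilon: 0.1734, parity_bytes: 2}
baseline:
  rate_max: {L: 150}   # ~1.92 bit/nt with a 1-byte index at L=150
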
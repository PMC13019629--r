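# Synthetic NISQ-grade device model (not calibration data of any real
# processor). Relaxation times follow the commonly quoted approximation
# T1 = 70 us, T2 = 50 us for contemporary superconducting devices; gate
# error probabilities, readout confusion and durations are typical
# published orders of magnitude for such hardware.
T1 = 70
T2 = 50
p_excited = 0
p1 = 3e-4
p2 = 3e-3
p01 = 0.02
p10 = 0.02
t_1q = 50
t_2q = 300
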
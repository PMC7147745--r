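g_leak = 30
v_rest = -70
c_membrane = 300
tau_membrane = 20
tau_ampa = 2
tau_gaba = 5
e_ampa = 0
e_gaba = -85
eta_decay_ip = 0.20000000000000001
eta_spike_ip = 0.066000000000000003
sigma_noise = 1
ou_tau = 20
refrac_E = 10
refrac_I = 2
th_floor = -80
ip_inhibitory = TRUE
A_plus = 0.050000000000000003
A_minus = 0.050000000000000003
tau_plus = 20
tau_minus = 20
w_total = 20
normalize = TRUE
dt = 0.10000000000000001
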
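mu_a_shift: 0.7
mu_a_c4: -0.00047
mu_a_c3: 0.009
mu_a_c2: -0.0307
mu_a_c1: 0.086
mu_a_c0: -2.317
mu_b_b2: 0.0047
mu_b_b1: -0.0866
mu_b_b0: -7.646
smoking_offset: 2
unilateral_oophorectomy_offset: 1
use_modifiers: TRUE
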
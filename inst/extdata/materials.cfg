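# Soft-tissue material blocks (mm-MPa-ms-g unit system).
# Muscle and skin/fat share coefficients; skin/fat switches the fibre
# contribution off via gamma = 1. bulk_k is the quasi-incompressibility
# penalty (not part of the published set; adjustable).

[muscle]
c1 = 2.5e-6
c2 = 6e-3
bulk_k = 0.1
c3 = 1e-3
c4 = 6
s_max = 0.1
dw_asc = 0.15
dw_dsc = 0.16
nu_asc = 2
nu_dsc = 4
lambda_opt = 1.3
gamma = 0
alpha = 0

[skin_fat]
c1 = 2.5e-6
c2 = 6e-3
bulk_k = 0.1
c3 = 1e-3
c4 = 6
s_max = 0.1
dw_asc = 0.15
dw_dsc = 0.16
nu_asc = 2
nu_dsc = 4
lambda_opt = 1.3
gamma = 1
alpha = 0

[liner]
c1 = 0.33
c2 = 0.01
bulk_k = 1
gamma = 1
alpha = 0
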
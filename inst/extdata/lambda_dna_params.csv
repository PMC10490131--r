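# Molecular parameters of completely monodisperse linear lambda-DNA
# solutions at four entangled concentrations (mg/mL), extracted from
# linear viscoelastic data. Units: eta_p in Pa s, tau_D and tau_R in s;
# chi_max and beta are dimensionless.
concentration,eta_p,tau_D,tau_R,chi_max,beta
0.82,12.4,87.0,11.0,18.0,20.0
1.01,22.6,109.0,14.0,18.0,13.0
1.55,474.4,1006.0,21.0,18.0,5.0
2.06,4811.7,4092.0,29.0,18.0,1.0
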
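variable,r,p
Ile,0.50,2.15e-21
Leu,0.50,2.15e-21
Val,0.54,2.15e-21
Gly,-0.43,1.55e-20
Ala,0.36,7.14e-14
Lys,-0.31,1.63e-10
Gln,-0.28,6.92e-09
Cit,0.26,6.36e-08
Phe,0.25,1.70e-07
Arg,-0.24,6.38e-07
Glu,-0.21,1.26e-05
Orn,-0.20,2.85e-05
Asp,-0.20,4.57e-05
Tyr,0.20,6.03e-05
Tau,-0.16,1.05e-03
Ser,-0.14,4.40e-03
Pro,0.13,1.04e-02
Trp,-0.11,2.56e-02
Met,-0.06,2.00e-01
Thr,0.05,2.82e-01
His,0.03,4.92e-01
Asn,0.02,6.14e-01
ABA,-0.01,8.89e-01
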
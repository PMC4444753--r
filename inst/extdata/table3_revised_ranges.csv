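name,lower,upper
CLF_UIM,7.87e-02,2.11e-01
KMNIS_I,1.33e+04,4.46e+04
VMAXNISF_THY_MI,1.22e+03,5.64e+03
KDEGT4F_MI,1.03e-04,2.52e-04
FRCONVT4_MI,5.67e-05,1.14e-04
BW_M,5.69e+01,8.33e+01
VDFT4_MI,7.69e-02,1.63e-01
QFTHY_MI,5.43e-03,2.66e-02
QFC_MI,9.48e+00,2.17e+01
CLFT4_MI,5.66e-05,3.13e-04
KPRODT4F_MI,6.85e-07,4.21e-06
FRCONVT4_FI,1.56e-05,2.24e-04
VDFT4_FI,1.21e-01,5.99e-01
KDEGT4F_FI,2.13e-03,5.47e-03
QFRP_MI,4.51e-01,8.37e-01
PFT4PLC_MI,5.93e-01,2.29e+00
PPLCPF_MI,1.65e-01,6.35e-01
PAFT4PLCF_MI,1.12e-04,4.48e-04
PAFPLCBTOT_MI,3.04e-02,1.30e-01
PPLC_MI,1.65e-01,6.35e-01
VMAXNISF_THY_FI,9.75e+02,6.82e+03
BW_F,2.53e+00,4.27e+00
PAFPLCTTOB_MI,3.04e-02,1.30e-01
KPRODT4F_FI,8.24e-05,3.18e-04
IODSTORES_MG_MI,6.81e+00,2.24e+01
VMAXNISF_PLC_MI,2.85e+02,1.22e+03
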
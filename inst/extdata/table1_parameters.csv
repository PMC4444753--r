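name,mean,cv,lower,upper,units,group,provenance
BW_F,3.4,0.13,2.5,4.3,kg,,literature
BW_M,72.3,0.14,52.5,92.1,kg,,literature
QFC_FI,32.6,0.28,14.8,50.4,L/h/BW^0.75,,literature
QFC_MI,15.6,0.20,9.5,21.7,L/h/BW^0.75,,literature
QFPLC_MI,0.1,0.29,0.04,0.2,fraction of maternal cardiac output,qflow_m,literature
QFTHY_FI,0.016,0.30,0.01,0.03,fraction of fetal cardiac output,qflow_f,assumed_default
QFTHY_MI,0.016,0.34,0.01,0.03,fraction of maternal cardiac output,qflow_m,literature
VDFT3_FI,0.3,0.50,0.01,0.6,fraction of fetal BW,,literature
VDFT3_MI,0.46,0.24,0.2,0.7,fraction of maternal BW,,literature
VDFT4_FI,0.36,0.34,0.1,0.6,fraction of fetal BW,,literature
VDFT4_MI,0.12,0.18,0.1,0.2,fraction of maternal BW,,literature
VFPLC_MI,0.009,0.16,0.01,0.01,fraction of maternal BW,vol_m,literature
VFPLCB_MI,0.233,0.19,0.1,0.3,fraction of placenta mass,plc_m,literature
VFPLCT_MI,0.767,0.19,0.5,1.1,fraction of placenta mass,plc_m,literature
VFPLS_FI,0.044,0.21,0.03,0.06,fraction of fetal BW,vol_f,literature
VFPLS_MI,0.055,0.14,0.04,0.07,fraction of maternal BW,vol_m,literature
VFTHY_FI,3e-04,0.50,1e-05,6e-04,fraction of fetal BW,vol_f,literature
VFTHY_MI,2.35e-04,0.57,1e-04,4e-04,fraction of maternal BW,vol_m,literature
VFTHYB_FI,0.276,0.30,0.1,0.4,fraction of fetal thyroid mass,thy_f,assumed_default
VFTHYB_MI,0.276,0.30,0.1,0.4,fraction of maternal thyroid mass,thy_m,assumed_default
VFTHYT_FI,0.724,0.30,0.3,1.1,fraction of fetal thyroid mass,thy_f,assumed_default
VFTHYT_MI,0.724,0.30,0.3,1.1,fraction of maternal thyroid mass,thy_m,assumed_default
VURINE,1.5,0.54,0.7,2.3,L,,literature
QFRP_MI,0.644,0.30,0.265328,1.022672,fraction of maternal cardiac output,qflow_m,assumed_default
QFSP_MI,0.24,0.30,0.09888,0.38112,fraction of maternal cardiac output,qflow_m,assumed_default
QFROB_FI,0.984,0.30,0.405408,1.562592,fraction of fetal cardiac output,qflow_f,assumed_default
VFRP_MI,0.1,0.30,0.0412,0.1588,fraction of maternal BW,vol_m,assumed_default
VFSP_MI,0.835765,0.30,0.34433518,1.32719482,fraction of maternal BW,vol_m,assumed_default
VFROB_FI,0.9557,0.30,0.39374840,1.51765160,fraction of fetal BW,vol_f,assumed_default
CLF_BIND_FI,3000,0.75,750,5250,L/h/BW^0.75,,literature
CLF_BIND_MI,3000,0.37,845,5155,L/h/BW^0.75,,literature
CLF_UIM,0.17,0.32,0.1,0.3,L/h/BW^0.75,,literature
CLFT3_MI,0.0027,0.77,0.0006,0.0048,L/h/BW^0.75,,literature
CLFT4_MI,1.85e-04,0.35,1e-04,3e-04,L/h/BW^0.75,,literature
FRCONVT4_FI,1.2e-04,0.44,0.2e-04,2.2e-04,dimensionless,,literature
FRCONVT4_MI,9e-05,0.24,5e-05,1.3e-04,dimensionless,,literature
IODSTORES_MG_FI,0.3,0.65,0.1,0.5,mg,,literature
IODSTORES_MG_MI,14.6,0.53,6.8,22.4,mg,,literature
KDEGT3F_FI,0.295,0.30,0.1,0.5,1/h/BW^0.75,,assumed_default
KDEGT3F_MI,0.002,0.30,0.001,0.003,1/h/BW^0.75,,assumed_default
KDEGT4F_FI,0.004,0.22,0.002,0.005,1/h/BW^0.75,,literature
KDEGT4F_MI,1.9e-04,0.30,1e-04,3e-04,1/h/BW^0.75,,assumed_default
KMNIS_I,31500,0.38,8038.8,54961.2,nM,,literature
KPRODT3F_FI,1.7e-05,0.30,1e-05,3e-05,1/h/BW^0.75,,assumed_default
KPRODT3F_MI,2.2e-07,0.41,4.4e-08,4.0e-07,1/h/BW^0.75,,literature
KPRODT4F_FI,1.7e-05,0.30,0.7e-05,2.7e-05,1/h/BW^0.75,,assumed_default
KPRODT4F_MI,2.5e-06,0.37,6.9e-07,4.2e-06,1/h/BW^0.75,,literature
PAFPLC_MI,0.005,0.62,0.002,0.008,L/h/BW^0.75,,literature
PAFPLCBTOT_MI,0.08,0.62,0.03,0.1,L/h/BW^0.75,,literature
PAFPLCTTOB_MI,0.08,0.62,0.03,0.1,L/h/BW^0.75,,literature
PAFT4PLCF_MI,2.8e-04,0.60,1e-04,4e-04,L/h/BW^0.75,,literature
PAFTHY_FI,1e-04,0.30,4e-05,1.6e-04,L/h/BW^0.75,,assumed_default
PAFTHY_MI,1e-04,0.30,4e-05,1.6e-04,L/h/BW^0.75,,assumed_default
PFT4PLC_MI,1.44,0.30,0.6,2.3,dimensionless,,assumed_default
PPLC_MI,0.4,0.30,0.2,0.6,dimensionless,,assumed_default
PPLCPF_MI,0.4,0.30,0.2,0.6,dimensionless,,assumed_default
PROB_FI,0.4,0.30,0.2,0.6,dimensionless,,assumed_default
PRP_MI,0.4,0.30,0.2,0.6,dimensionless,,assumed_default
PSP_MI,0.18,0.30,0.1,0.3,dimensionless,,assumed_default
PTHY_FI,0.15,0.30,0.1,0.2,dimensionless,,assumed_default
PTHY_MI,0.15,0.30,0.1,0.2,dimensionless,,assumed_default
PTT4PLC_MI,1.44,0.30,0.6,2.3,dimensionless,,assumed_default
TLEN_I,1,0.30,0.4,1.6,h,,assumed_default
VMAXNISF_PLC_MI,750,0.62,285,1215,nmol/h/BW^0.75,,literature
VMAXNISF_THY_FI,3900,0.75,975,6825,nmol/h/BW^0.75,,literature
VMAXNISF_THY_MI,3800,0.45,478,7122,nmol/h/BW^0.75,,literature
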
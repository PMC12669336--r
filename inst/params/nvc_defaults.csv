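name,value,units,source
F_KIR,750,-,literature
g_KIR,0.09,-,literature
gamma_i,1970,mV/uM,literature
z1,4.5,mV/mM,literature
z2,112,mV,literature
K_p,3.5,mM,literature
P_Ca,5e-5,1/ms,literature
G_v,1e-3,1/ms,literature
P_IP3,5e-5,1/ms,literature
buf_free,0.01,-,paper
F_i,1e-3,uM/ms,calibrated
K_ri,1,uM,literature
J_leak_i,2.5e-5,uM/ms,literature
k_ex_i,4e-4,1/ms,calibrated
B_i,2.5e-4,uM/ms,calibrated
c_bi,1,uM,literature
k_voc,1e-6,uM/(mV ms),literature
v_voc0,-45,mV,literature
F_j,2.3e-4,uM/ms,literature
K_rj,1,uM,literature
k_ex_j,1.7e-3,1/ms,literature
J_EC_IP3,1.8e-4,uM/ms,literature
k_deg_ip3,1e-4,1/ms,literature
tau_v,25,ms,literature
v_L_i,-60,mV,literature
v_K_i,-90,mV,literature
G_KIR_eff,3.4e-5,1/ms,literature
G_BK,2e-3,1/ms,literature
v3_BK,-35,mV,literature
v4_BK,14,mV,literature
eps_bk,0.45,-,literature
alpha_bk,0.55,-,literature
gamma_bk,-0.55,1/uM,calibrated
s_BK,20,mV,calibrated
gamma_cross,1.7e-2,1/(uM3 ms),literature
K2_base,5e-4,1/ms,literature
K3_cb,4e-4,1/ms,literature
K4_cb,1e-4,1/ms,literature
K7_cb,1e-4,1/ms,literature
delta_i,58.1,-,literature
k_mlpc_b,8.6e-6,1/ms,literature
k_mlpc_c,3.27e-5,1/ms,literature
K_m_mlcp,5.5,uM,literature
Ca_ref_max,1.0,uM,calibrated
eta_wall,1e4,Pa s,literature
E_pas,6.6e4,Pa,literature
E_act,2.33e5,Pa,literature
R0_pas,20,um,literature
R0_act,12,um,literature
dp_wall,4000,Pa,literature
R_init,20,um,literature
V_max_NO_n,4.22e-3,uM/ms,literature
K_m_O2_n,243,uM,literature
O2_n,200,uM,literature
K_m_LArg_n,1.5,uM,literature
LArg_n,100,uM,literature
K_mA,650,uM,literature
K_mB,2800,uM,literature
G_M,46,pS,literature
PCa_PM,3.6,-,literature
Ca_ex_nmda,2000,uM,literature
M_mono,1.3e5,uM,literature
alpha_v_nmda,0.08,1/mV,literature
beta_v_nmda,60,mV,literature
k_act_nNOS,5e-5,1/ms,calibrated
k_deact_nNOS,1e-4,1/ms,literature
nNOS_tot,1,uM,literature
V_max_NO_j,1e-3,uM/ms,literature
K_m_O2_j,7.7,uM,literature
O2_j,200,uM,literature
K_m_LArg_j,1.5,uM,literature
LArg_j,100,uM,literature
e_base,0.1,uM,literature
e_Ca,0.5,uM,literature
K_eCa,0.3,uM,literature
g_wss,0.4,uM,literature
K_wss,2,Pa,literature
Q_wss,8.19e-8,cm3/s,literature
mu_wss,3.5e-3,Pa s,literature
D_NO,3.3,um2/ms,literature
dx_na,25,um,paper
dx_as,25,um,literature
dx_se,25,um,literature
lam_NO_n,1e-3,1/ms,literature
lam_NO_a,1e-3,1/ms,literature
lam_NO_s,1e-3,1/ms,literature
lam_NO_e,1e-3,1/ms,literature
V_cGMP,1.26e-3,uM/ms,literature
K_NO_sGC,0.2,uM,literature
k_pde,1.5e-4,1/ms,literature
C_post,1,uF/cm2,literature
g_L_post,0.1,mS/cm2,literature
V_L_post,-70,mV,literature
g_ampa,0.35,mS/cm2,literature
K_ampa,0.5,mM,literature
V_ampa,0,mV,literature
g_nmda,0.15,mS/cm2,literature
V_nmda,0,mV,literature
g_gabaa,0.25,mS/cm2,literature
K_gabaa,0.5,mM,literature
V_gabaa,-70,mV,literature
g_gabab,0.05,mS/cm2,literature
K_gabab,0.5,mM,literature
V_gabab,-90,mV,literature
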
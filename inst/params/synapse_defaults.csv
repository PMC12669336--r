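name,value,units,source
C_m,1,uF/cm2,literature
g_Na,120,mS/cm2,literature
g_K,36,mS/cm2,literature
g_L,0.3,mS/cm2,literature
V_Na,45,mV,literature
V_K,-82,mV,literature
V_L,-59.4,mV,literature
I_app_glu,10,uA/cm2,literature
I_app_gaba,8,uA/cm2,literature
rho_Ca,3.2,1/um2,literature
g_Ca,2.3,fA/mV,literature
V_mCa,-17,mV,literature
k_mCa,8.4,mV,literature
tau_mCa,1,ms,literature
c_ext,2000,uM,literature
c_i_rest,0.1,uM,literature
A_btn,1.13,um2,literature
V_btn,0.113,um3,literature
v_leak,5e-5,1/ms,literature
K_PM_Ca,0.5,uM,literature
v_PM_Ca,50,fA/um2,calibrated
c1_er,0.01,-,literature
v1,6e-3,1/ms,literature
v2,6e-4,1/ms,calibrated
v3,5.3e-4,uM/ms,calibrated
k3,0.1,uM,literature
d1,0.13,uM,literature
d2,1.049,uM,literature
d3,0.9434,uM,literature
d5,0.08234,uM,literature
a2,2e-4,1/(uM ms),literature
c_ER0,120,uM,calibrated
p0,0.16,uM,literature
v_g,6.2e-5,uM/ms,literature
k_g,0.2,mM,literature
tau_p,1.4e-4,1/ms,literature
alpha_s,0.3,1/(uM ms),literature
beta_s,3,1/ms,literature
gamma_s,30,1/ms,literature
delta_s,8,1/ms,literature
n_vesicles,2,-,literature
a1_sp,15,uM,literature
a2_sp,2,uM,literature
a3_sp,0.003,1/ms,calibrated
tau_rec,800,ms,literature
tau_inact_glu,3,ms,literature
tau_inact_gaba,10,ms,literature
lockout_glu,6.34,ms,paper
lockout_gaba,7.2,ms,paper
n_v,0.05,1/ms,calibrated
g_v_glu,60,mM,paper
g_v_gaba,20,mM,paper
g_c,1,1/ms,literature
n_av,1e-3,1/ms,calibrated
g_av_glu,60,mM,paper
g_av_gaba,20,mM,paper
g_ac,0.1,1/ms,literature
r_Ca,6e-3,1/ms,literature
v_ER_a,9e-4,uM/ms,literature
K_ER_a,0.1,uM,literature
r_L,1.1e-4,1/ms,literature
c0_a,2,uM,literature
c1_a,0.185,-,literature
v_beta,5e-4,uM/ms,literature
K_R,1.3,uM,literature
K_p_a,10,uM,literature
K_pi,0.6,uM,literature
v_delta,5e-5,uM/ms,literature
k_delta,1.5,uM,literature
K_PLCdelta,0.1,uM,literature
v_3K,2e-3,uM/ms,literature
K_D,0.7,uM,literature
K_3,1,uM,literature
r_5P,5e-5,1/ms,literature
N_IP3,20,-,literature
k1_minus,4e-4,1/ms,paper
k2_minus,1e-3,1/ms,paper
k3_minus,1e-2,1/ms,paper
Kd1_a,0.108,uM,paper
Kd2_a,0.4,uM,paper
Kd3_a,0.8,uM,paper
c_a_thresh,0.3,uM,literature
tau_rec_a,5000,ms,literature
tau_inact_a,1000,ms,literature
k_rel_a,1e-3,1/ms,calibrated
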
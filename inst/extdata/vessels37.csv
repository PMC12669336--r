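id,name,parent_ids,child_ids,L_cm,R0_cm,h0_cm,E_Pa,outlet_flag,provenance
1,ascending_aorta,,2:3,4.0,1.2,0.163,4.0e5,0,literature
2,aortic_arch_I,1,9:10,2.0,1.12,0.126,4.0e5,0,literature
3,brachiocephalic,1,4:5,3.4,0.62,0.080,4.0e5,0,literature
4,subclavian_R,3,6:14,3.4,0.423,0.067,4.0e5,0,literature
5,common_carotid_R,3,7:8,17.7,0.25,0.063,4.0e5,0,literature
6,brachial_R,4,,42.2,0.403,0.067,4.0e5,1,literature
7,int_carotid_R_I,5,21,17.7,0.2,0.045,8.0e5,0,literature
8,ext_carotid_R,5,,17.7,0.15,0.042,8.0e5,1,literature
9,common_carotid_L,2,11:12,20.8,0.25,0.063,4.0e5,0,literature
10,aortic_arch_II,2,13:15,3.9,1.07,0.115,4.0e5,0,literature
11,int_carotid_L_I,9,26,17.7,0.2,0.045,8.0e5,0,literature
12,ext_carotid_L,9,,17.7,0.15,0.042,8.0e5,1,literature
13,subclavian_L,10,16:17,3.4,0.423,0.067,4.0e5,0,literature
14,vertebral_R,4,34:35,9.866,0.136,0.034,8.0e5,0,paper
15,thoracic_aorta,10,,15.6,0.999,0.110,4.0e5,1,literature
16,brachial_L,13,,42.2,0.403,0.067,4.0e5,1,literature
17,vertebral_L,13,36:37,9.866,0.136,0.034,8.0e5,0,paper
18,basilar,34:36,19:20,2.9,0.162,0.040,1.6e6,0,literature
19,pca_P1_R,18,25,0.5,0.107,0.039,1.6e6,0,literature
20,pca_P1_L,18,30,0.5,0.107,0.039,1.6e6,0,literature
21,int_carotid_R_II,7,22:23:24,0.5,0.2,0.045,1.6e6,0,literature
22,mca_R,21,,11.9,0.143,0.042,1.6e6,1,literature
23,aca_A1_R,21,31:32,1.2,0.117,0.042,1.6e6,0,literature
24,pcoa_R,21,25,1.5,0.073,0.028,1.6e6,0,literature
25,pca_P2_R,19:24,,8.6,0.105,0.039,1.6e6,1,literature
26,int_carotid_L_II,11,27:28:29,0.5,0.2,0.045,1.6e6,0,literature
27,mca_L,26,,11.9,0.143,0.042,1.6e6,1,literature
28,aca_A1_L,26,33,1.2,0.117,0.042,1.6e6,0,literature
29,pcoa_L,26,30,1.5,0.073,0.028,1.6e6,0,literature
30,pca_P2_L,20:29,,8.6,0.105,0.039,1.6e6,1,literature
31,acoa,23,33,0.3,0.074,0.042,1.6e6,0,literature
32,aca_A2_R,23,,10.3,0.12,0.042,1.6e6,1,literature
33,aca_A2_L,28:31,,10.3,0.12,0.042,1.6e6,1,literature
34,vertebral_R_distal,14,18,4.930,0.136,0.034,8.0e5,0,paper
35,dvc_branch_R,14,,6.0,0.08,0.034,8.0e5,1,paper
36,vertebral_L_distal,17,18,4.930,0.136,0.034,8.0e5,0,paper
37,dvc_branch_L,17,,6.0,0.08,0.034,8.0e5,1,paper
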
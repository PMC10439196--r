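preset,a,b,c,m,f,d,sigma1,sigma2,eta1,eta2,L,n,delta_tau,N,P0,Q0,perturb,regime
fig1_coexistence,1.1,0.7,2.1,1,0.79,0.5,0.1,0.1,0.01,0.01,30,100,0.1,5000,0.6,0.4,0,coexistence
fig3_oscillation,1.1,0.7,2.1,1,0.80,0.5,1,1,0.01,0.01,30,100,0.1,5000,0.6,0.4,0,oscillatory
fig5_predator_free,1.1,0.7,2.1,1,0.4,0.5,0.1,0.1,0.01,0.01,30,100,0.01,5000,0.6,0.4,0,predator_free
fig7_extinction,1.1,0.7,2.1,1,0.84,0.5,0.1,0.1,0.01,0.01,30,100,0.1,5000,0.6,0.4,0,extinction
fig9_stiff_diffusion,1.1,0.7,2.1,1,0.7,0.5,1,1,0.01,0.01,10,60,0.1,5000,0.6,0.4,0.01,sfe_divergence_demo
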
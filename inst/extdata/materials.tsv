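# Canonical material database: one row per medium.
# rho_g_cm3: mass density; beta_per_K: volumetric thermal expansion coefficient;
# v_m_s: speed of sound; cp_J_K_kg: heat capacity at constant pressure;
# gamma: Grueneisen coefficient; z_Ns_m3: acoustic impedance;
# alpha_th_m2_s: thermal diffusivity.
# z_over_a and i_ev (mean excitation energy, ICRU 49) feed the Bethe
# stopping-power model and are not part of the acoustic table.
name	rho_g_cm3	beta_per_K	v_m_s	cp_J_K_kg	gamma	z_Ns_m3	alpha_th_m2_s	z_over_a	i_ev
water	1	210e-6	1500	4180	0.11	1.5e6	0.15e-6	0.55509	75
gold	19.3	42.6e-6	3240	128.8	3.47	6.3e7	128e-6	0.40108	790
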
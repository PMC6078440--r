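# Random-coil backbone amide chemical-shift coefficients (version 1.0)
# Neighbor-corrected scheme: delta_rc(i) = intrinsic(aa_i)
#   + sum_{k in -2,-1,+1,+2} corr_{aa_(i+k), k}
#   + tc(aa_i) * (T - 298.15 K) / 1000
#   + pH term (Henderson-Hasselbalch, see package documentation).
# Reference state: 298.15 K, fully deprotonated Asp/Glu/His side chains,
# cysteines oxidized (cystine). Values in ppm; tc in ppb/K.
# Columns *_imK / *_ipK: contribution to residue i when this amino acid
# occupies position i-K / i+K. Proline rows carry neighbor corrections
# only; its own amide entries are reported missing.
aa	H	N	tcH	tcN	H_im2	H_im1	H_ip1	H_ip2	N_im2	N_im1	N_ip1	N_ip2	pKa	dH_self	dN_self	dH_nb1	dN_nb1	dH_nb2	dN_nb2
A	8.24	123.80	-4.6	-2.5	0.01	-0.05	-0.03	0.00	0.05	-0.30	-0.15	0.02	0	0	0	0	0	0	0
C	8.43	118.80	-4.8	-2.6	0.02	0.05	0.01	0.01	0.10	0.55	0.10	0.05	0	0	0	0	0	0	0
D	8.34	120.40	-4.5	-2.4	0.01	0.03	0.06	0.01	0.08	0.35	0.25	0.03	3.90	0.08	0.90	0.03	0.25	0.01	0.08
E	8.42	120.20	-4.6	-2.5	0.01	0.02	0.04	0.01	0.06	0.25	0.20	0.03	4.30	0.06	0.60	0.02	0.20	0.01	0.06
F	8.30	120.30	-4.9	-2.7	-0.04	-0.08	-0.10	-0.03	0.10	0.50	-0.25	-0.08	0	0	0	0	0	0	0
G	8.33	108.80	-4.4	-2.3	0.00	-0.06	-0.05	-0.01	-0.15	-0.55	-0.40	-0.05	0	0	0	0	0	0	0
H	8.42	118.20	-4.7	-2.6	0.02	0.04	0.03	0.01	0.08	0.30	0.15	0.04	6.45	0.15	1.20	0.06	0.40	0.02	0.12
I	8.00	119.90	-4.7	-2.6	0.00	-0.02	-0.04	-0.01	0.12	1.90	-0.20	0.02	0	0	0	0	0	0	0
K	8.29	120.40	-4.6	-2.5	0.01	0.01	0.02	0.00	0.05	0.20	0.10	0.02	0	0	0	0	0	0	0
L	8.16	121.80	-4.6	-2.5	0.00	-0.03	-0.02	0.00	0.06	0.50	-0.10	0.02	0	0	0	0	0	0	0
M	8.28	119.60	-4.6	-2.5	0.01	0.00	0.00	0.00	0.05	0.30	0.05	0.02	0	0	0	0	0	0	0
N	8.40	118.70	-4.5	-2.4	0.01	0.04	0.05	0.01	0.06	0.30	0.20	0.03	0	0	0	0	0	0	0
P	8.30	137.00	-4.5	-2.5	0.02	0.10	0.08	0.02	-0.20	-1.00	0.85	0.10	0	0	0	0	0	0	0
Q	8.32	119.80	-4.6	-2.5	0.01	0.02	0.03	0.01	0.05	0.25	0.12	0.02	0	0	0	0	0	0	0
R	8.23	120.50	-4.6	-2.5	0.01	0.01	0.02	0.00	0.05	0.25	0.10	0.02	0	0	0	0	0	0	0
S	8.31	115.70	-4.5	-2.4	0.01	0.03	0.04	0.01	0.02	0.50	0.15	0.03	0	0	0	0	0	0	0
T	8.15	113.60	-4.5	-2.4	0.01	0.02	0.03	0.01	0.05	1.20	0.10	0.03	0	0	0	0	0	0	0
V	8.03	119.20	-4.7	-2.6	0.00	-0.02	-0.04	-0.01	0.10	1.80	-0.20	0.02	0	0	0	0	0	0	0
W	8.25	121.30	-5.0	-2.8	-0.05	-0.10	-0.12	-0.04	0.08	0.45	-0.30	-0.10	0	0	0	0	0	0	0
Y	8.12	120.30	-4.9	-2.7	-0.04	-0.07	-0.09	-0.03	0.08	0.45	-0.22	-0.07	0	0	0	0	0	0	0
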
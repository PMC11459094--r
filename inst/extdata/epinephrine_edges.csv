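from,to
C_methyl,N
N,C_beta
C_beta,C_alpha
C_alpha,O_beta
C_alpha,C1_ring
C1_ring,C2_ring
C2_ring,C3_ring
C3_ring,C4_ring
C4_ring,C5_ring
C5_ring,C6_ring
C6_ring,C1_ring
C3_ring,O_meta
C4_ring,O_para
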
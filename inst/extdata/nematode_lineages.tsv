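species	lineage
C_elegans	Nematoda,Chromadorea,Rhabditoidea,Caenorhabditis
C_briggsae	Nematoda,Chromadorea,Rhabditoidea,Caenorhabditis
C_remanei	Nematoda,Chromadorea,Rhabditoidea,Caenorhabditis
C_brenneri	Nematoda,Chromadorea,Rhabditoidea,Caenorhabditis
C_japonica	Nematoda,Chromadorea,Rhabditoidea,Caenorhabditis
C_sinica	Nematoda,Chromadorea,Rhabditoidea,Caenorhabditis
D_pachys	Nematoda,Chromadorea,Rhabditoidea
S_ratti	Nematoda,Chromadorea
A_ceylanicum	Nematoda,Chromadorea
B_malayi	Nematoda,Chromadorea
A_suum	Nematoda,Chromadorea
T_spiralis	Nematoda,Enoplea
T_muris	Nematoda,Enoplea
C_muris	outgroup
P_falciparum	outgroup
B_xinjiang	outgroup
E_necatrix	outgroup
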
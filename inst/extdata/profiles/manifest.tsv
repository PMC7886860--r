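name	file	marker_class	group_tags
TerL	TerL.synthetic.afa	structural	Alpha-Gamma,Beta,Delta,Epsilon,Zeta
MCP	MCP.synthetic.afa	structural	
portal	portal.synthetic.afa	structural	
gene75	gene75.synthetic.afa	structural	
gene74	gene74.synthetic.afa	structural	
IHF_53	IHF_53.synthetic.afa	structural	
Ttub	Ttub.synthetic.afa	structural	
Tstab	Tstab.synthetic.afa	structural	
PDDEXK_a	PDDEXK_a.synthetic.afa	replication	
primase	primase.synthetic.afa	replication	
DnaB	DnaB.synthetic.afa	replication	
Hint	Hint.synthetic.afa	insert_domain	
endonuclease	endonuclease.synthetic.afa	insert_domain	
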
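>Alpha-Gamma
MFLTEADWHLDSAEIKTEDEKAISAGDTRLWSADNQAELAGRESETFGQRAPRVRNVNPVWNVLYWTRWIGLHSKFFVLTSVDLDNSRGQMRMWLVADGHSWNTFCHKQGSMLEVYKPTAPAANALCACNGIKLQTNYHSSQGGADRDQA
>Beta
MKLESADNIFTLAEVAKEDEKAISNETFRLWSADNQLEWAKDESETFRQRFCYWWNVNPCHNVLMETQWGGLHSKLGVLTSVSLRPGSVQMRGWLHAACHSWNTMCMKRPSMLEVPPPPAVSAGSLMANNIIKHQMNDIYSQDTCDRKQA
>Delta
MKLSSADVIMDFAEIKMEDSKAASAETSRSIFAGNFLELAGRESEDFKQRFPYWRNVECVHNVLMNTRWMLLHSKLLVFIRCSLLTHRRQMRGWYYLDCHSWDTVCWKRGSMSEVPPPPAPPWGALAAANGCMLFTNDHSSQGGQFLKQA
>Epsilon
MKLHSADVILDFAEIKWELEKNDHAETFRSWSVENQWYLSNRESETGRQRFTYKNNWNTVHTVLMETRWPYEHSKLSVFVSVSLLPGRDQMRGWLMADCISWNTMCKRRGSCGEVCPPPAMQAGALAAMNGIKLETNDHSRQGGADRKQA
>Zeta
MKHTSAYMILWDADIKMEDEPAESFEGFRLWAAGNQHMLAGRESETFYQRFPYWRMVNPCSNVMMETRWPGLHSKLLVLTSVSLLPGIAQMRWILVADCYSWNTMCLKRGSPLEHPPKPMPSAQAGAAANGRAFATNDHSSQGMADDDMA
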
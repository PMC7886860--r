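>TerL_AlphaGamma_ref
MFLTEADWHLDSAEIKTEDEKAISAGDTRLWSADNQAELAGRESETFGQRAPRVRNVNPVWNVLYWTRWIGLHSKFFVLTSVDLDNSRGQMRMWLVADGHSWNTFCHKQGSMLEVYKPTAPAANALCACNGIKLQTNYHSSQGGADRDQA
>TerL_Beta_ref
MKLESADNIFTLAEVAKEDEKAISNETFRLWSADNQLEWAKDESETFRQRFCYWWNVNPCHNVLMETQWGGLHSKLGVLTSVSLRPGSVQMRGWLHAACHSWNTMCMKRPSMLEVPPPPAVSAGSLMANNIIKHQMNDIYSQDTCDRKQA
>TerL_Delta_ref
MKLSSADVIMDFAEIKMEDSKAASAETSRSIFAGNFLELAGRESEDFKQRFPYWRNVECVHNVLMNTRWMLLHSKLLVFIRCSLLTHRRQMRGWYYLDCHSWDTVCWKRGSMSEVPPPPAPPWGALAAANGCMLFTNDHSSQGGQFLKQA
>TerL_Epsilon_ref
MKLHSADVILDFAEIKWELEKNDHAETFRSWSVENQWYLSNRESETGRQRFTYKNNWNTVHTVLMETRWPYEHSKLSVFVSVSLLPGRDQMRGWLMADCISWNTMCKRRGSCGEVCPPPAMQAGALAAMNGIKLETNDHSRQGGADRKQA
>TerL_Zeta_ref
MKHTSAYMILWDADIKMEDEPAESFEGFRLWAAGNQHMLAGRESETFYQRFPYWRMVNPCSNVMMETRWPGLHSKLLVLTSVSLLPGIAQMRWILVADCYSWNTMCLKRGSPLEHPPKPMPSAQAGAAANGRAFATNDHSSQGMADDDMA
>TerL_syn01
MKLTSAMVILDFMCIKMEDEKAISAETFRLWSAGNQLELAGRDSETFRQRFWYWRNVNPVHNVLMETRWPYLHSKLLVLLSVNLLPGRGQMRGWTVADCHSWNTMCHKRLSMLGVPPIPAPSAGALAAMNGIKLQTNDHSSKGGAYRKQA
>TerL_syn02
MELTSADVILDFAEIKMEDEKQIFAWTFRLWSAGNQLELAGRESETFRQRFPYGRNVNPVHNVLMETRWPGLHSKLLVLTTVSLLPGRGQMRGPLVADCHSWNTMVHKRGSMLEVGEPPCPSAGALAAANGIKLQWNDHSSQGNDDRKQN
>TerL_syn03
MKLTSADVELDFAEWHMEDEKAISAETFRDWSAGNQLGLAGRESEWFRQRFPYWRNVNPVHNVLMETRSPGLHFKLLVLTNVSLLPGRGQMRGWLVAACHSWNTMCHKRGLMLEVPPPPAPSAGALAAAVGIKLQTNDHISQGGADNKQV
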
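>gene75_syn01
MTKKGGRAFESESAAFKALYQSSEVRVLYTATWSAELHMNGYHLAARTQEASKEYDYTFSLVDSAHGEKI
>gene75_syn02
STKRGGRARESEVAAFRALIQRSLVRVLYTPTGIAELHMNGYHTAAATVEASGEYDCVFSLVDSAQGEHM
>gene75_syn03
MCKKGGRARESESAAFRALFVRSLVRVLYTATGCAELHHNGYHLAAARVEAHKEYDYVWSLVDRADGEKI
>gene75_syn04
KTKKGMRRRPSESAAFIYLYQRSLDRVRATATGIMELHMNGYHLAAATVEASKEYDYVFSLVDSAQGEKI
>gene75_syn05
MTPKGGRARESESKALRALYQRSLKRVLYTATGIAWLHMWGYHAAAATHENSKEYDYVFSLVDSAQGVKI
>gene75_syn06
MTKKGGRFRFSESAALRILFQRSLVRVLYTATRIAELHMNGYHLAAAWVEASKEYDSVFSLVDSPRGEKI
>gene75_syn07
MTKKGGRARFHESAHFRALYQRSLVRVLYTAGGIAELHMNIYELAAATVEGSKEYDWVFALGDSAQGEKI
>gene75_syn08
MTKKGGRARESEAAAFRADYQRSLWRVIVRATGIPELHCMGYHLAAATVEASKEYDYVFSLVDSAQGEKF
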
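>IHF_53_syn01
MGCDSVLILVGKVLPYIPNDIVEVIQARNFEDKVHRLISGEFEDQKIEGTSIEQVILNGL
>IHF_53_syn02
TSSDSVQRLVGKVLPYFPYDIVEVIQARNFEDLTIRLWSGEFADQKCEATSIRQVECNGL
>IHF_53_syn03
MFSDYVLRLVVKVLPYIPNDIVHDIQYRNFEDLVIRLISGEFQDQKIEASSFRQVELNTL
>IHF_53_syn04
MQSCMVLRLEFKVLPYIPNDIVEVIQAANFEDNVIRLKSGEFADQKIEATSPRQVELNGL
>IHF_53_syn05
MFSYSVLRWVGKVLPYIPNDIVEVIQARNFEYLVIRLIYGEFADQQIETTEIRQVEQVGL
>IHF_53_syn06
MFSCSVLRLVGKQIPYIDNDIVEVIAHPNEEDLVIRLISGEFADQKIEATSHRQVELNGL
>IHF_53_syn07
WVADSVLRLVGKVLAYKPNDIVEVIQAVNFEDLVIRLFSGEFADQKMEATSIPQVELNGL
>IHF_53_syn08
VFSDSVWWLVRKVLPYIPNDIVNVIQARMFEDLVIRLTSGEFWDQKIEATSILQVELNGL
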
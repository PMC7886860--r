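>endonuclease_syn01
MLIVDYRQHSQSIQATGDRSSFRKDHQVEDNLLITAFHLEEAKAYASFEKIIWEDLGGPGCLVNVVLFEPHLTHQIIQPG
>endonuclease_syn02
MVILDKWQHSRSIQALGDRNNCRKDQQVEDNLLITASHWEEAKAYAEFESIIWEDLDDPGCRVNVVHPELHLTHQSEQAG
>endonuclease_syn03
MLILDKRQHSQSIQATGDRNNFRKDPQVEDPLLHTVSHLEEIKAYASFEHIGWEDLGDPYCRVHVVLAELHHTHQSIIPL
>endonuclease_syn04
GLISDKRQGSQSIQATQDRMNFRKDPQVEDSLLITASHLEEANAYASYESFIWCDLGDPWIRVNVVLPELHLTHQSIQPG
>endonuclease_syn05
MIILRKRVHSQSCQATGDDNNFRKDEQVEDNLLITASHLEEAKAYASLESFIWEDLGDPKCRRNVVLPRLHLTHQSIQVG
>endonuclease_syn06
MLILDKRVHSQTINATGDRNNDRKDPQVEMNLLITCSNLEEAKAYASFVSIIWEDLGDPGCRVLVVSPELILTNQSIQPG
>endonuclease_syn07
ILILDKRQHSQSIQATSDRNNFRKDPQVEDNLLIRDHHLEEAKAYASFESEIREDRVDPGCRQNVKLPFLHLTHQSIQPG
>endonuclease_syn08
MLILDKRSHSQSIQATGDRNNFRKDPQVEDNLHITAVHVEELKAYASFECIIWNDLCRPGCRVNGVLPKLHLTHQSLQPG
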
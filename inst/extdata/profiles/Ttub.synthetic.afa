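>Ttub_syn01
MHTGDACRDKQFGSNIQFTHPDASTYDHVWLIMMESKELIEKCDHHNVRRGVLSSMLQREEQFLQISAGNTLKAGDQSGHIELLNNSLAM
>Ttub_syn02
MHTGDANRDTQFGSNIFFIHPDTSTRDHVWNISDESKESIEICDHHTVRRGVLSSMMQRHEQSLQWEAGGTLKAGSQSGHIKLLPYSLAL
>Ttub_syn03
MHTYDANRDTQRGWNFQFCHPDASTYDRVGLIMDESKESIEICLGHTVRRGVLSSMLARGEQSLQISAGGTVKAAHQSGHIELLPNSLDL
>Ttub_syn04
MHFGAANRDTQFGSNIQFCHQDASVYDHKWLIMDEMKESIEIRDGHFVRRGMLSSMLQREELSLQISAGGTLKACNQSGSTGLLPYSLAL
>Ttub_syn05
MHTGDANRDTQFGSTIQFCHPDCSHYDHVWLRMDESKESIENTDLHFVWRGVLSSMLQVEEQRLQISAGGTLKAGHGFGHIEWLPYSQAL
>Ttub_syn06
MHTGDADRDTQFGYNICFTHPDPSTNDHVWLIMDESKESIEICDGHFVRRGSLSSMLQRMMQSLQILAGGTLKAGSQLGHSELPPYSLAL
>Ttub_syn07
MHTGDCNRDTQFGSSIQFCHPDASTYDHVWLFMAESEESIRCLDGMFVARGVLSKMLQREEQSLQISAGGTLKAGHQSNHIELLPISLYL
>Ttub_syn08
MHTGEANRDTQFGPNIQFSHQDASTYDEVWLIMDESKESIEICDGIWVMRMVLSSMLQREEQSLQIQAGGTLDAGHRIGYIELLPYSLAL
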
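>primase_syn01
MHSLRPTYGLVSKQPGTSGFPATEETLYYDKSGKYIKVIPAQLGSEATSASVDMYDIATLIYAEGSFRIDADHGNVMMCAGKAEHMNSEIAGPGGKAPICTILGNLIATQ
>primase_syn02
MHSIRDTYGLPSKVPYPSGFPAREETLVYDKSGKYIGVVPAQLGSMATSASVLMGDIATDPHVEGSFRITADHVNFMMCAGKKEHMNSLLQGPGLKADIFTILQNLEATK
>primase_syn03
MRSDRDTDGLPSKSPLPSGCPAFEETLVYNPSGKTIKVVPFQLGSRATTASVLMGDIAQLIPVEGSFRITADHVNVMMCAGKAEHMNSELIGPGGKAPIFTILWNLEFTK
>primase_syn04
MHSLRDTYGLPSKSPGPSGFPATGMTLVSDKSGKYIKVVPAQCGCEATHASMVMGDIATLIYVEGSFWITADHVNVMMRASKAEHMNSELIGPMGKAAIFLILGNYGATK
>primase_syn05
MHSLRDTEGLPAKYPGPSAFPATEENLVYDKSGKYINVVPAQFGCEATSASVLMQDIATLIYVEGSRDITADHVNVMMCVGKAEHMNSELVNCGGKAPITTILGNLEATK
>primase_syn06
MGSERDTGGLPSKSHGPSGFPATGETLVYDKSGKYIKVVPVQLGSEATSASVLMGDHATLIEHEGSFRITADPVNVMMCAGKGEFMHSELIVPGKKAPIFTILGNLPATK
>primase_syn07
RHSLRDTYGLPSKSPGPSGFYAPPETLAYDKSGKYIKVVPAQLGSEATSMSVLMGDIATLIYVEGSFRDTRDHVTVMMCALKAEHMNEEAIGPGWKAPCFMILGNAEATK
>primase_syn08
MHSLRDTYGLPSKTPARTGFPATEETLVYDKSWKYIKVVPASLGSEATSASVLMGDIATLIYVECSERMTADLVNVMMILGKCEHMNSELEGPRGKAPIFTILGNLEAIK
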
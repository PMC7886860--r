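>DnaB_syn01
MAEQLLLSMDKASLKDCTMRICAGFINTHHQMTLLPGICVTMEALQALNRPQSHTIDVQFGYKCYNGLGMIKNLQRQSNPPGYFLSSWYHWTNLIQKVARPAAGILFGHK
>DnaB_syn02
MHSQLLLSMDKAGLKDVKMRIASGFINTHHQMTLLPGICVTIEIYQAMNSMEGHHDDVQVYYKCYNGLGPIKGLLRQSNPPGYFLMSRYHWTNLIEKVEKPARHKLCGFK
>DnaB_syn03
MWEAMLLSMDKANLLDVHMNICSGFINTHHQPTLLVGFCVTIEALQAMNSPESGTDDVQFGYKCYVGLFPIKGLLRQKNPPGYFLSSRYHWTNLIQKVDRPAAGRLCGFK
>DnaB_syn04
MAEPLLLSMDKAYLKRVTMRICSGFYNTHHQPTLLPGICVTIFALQIMNSPESMCDDVKFGYVCYNGLGPIKGLLRQSNPPIYFLSSRYHYTQLIQKVERPAAGKLDMFK
>DnaB_syn05
YAEQLLTSIDKAGLKLVTTRITAGFINTHHQMTKLPGICVEQEDLQAMNSPESHTKDVQFGYKCYNGLGPPKGLLRQSNPPGYFLSSRYHNTNDIMKVERPAAGKLCGFK
>DnaB_syn06
MAEAMLLSMDKAGLKDVTMFICSGFINTHHQMALLPGICVTILALQDMNSPESHGDKVQFGYKCYAGLGPIKGLLRQYNPPLRFMSSRYHWTNLIQKVERPHATKRCGFK
>DnaB_syn07
MAECCLLNMIKAGQKDVDWRICSGFIITHHQMTLLPGICDTIEALQAMNSMESHIDDVQFYYKCYNGLGPINILLRQSNPPGYFLSSRYHWTNLIQKVERPMAGKACGFK
>DnaB_syn08
MAEQLLVSMDKCGGKDVEMRIISGFISTHNQHTLLPGICVTIEALQAMNSPESHTDDAQFGYKCYNGLGSIKGLLRQRNPPGYFLSSRLHWTNVIQKVERPNAGKYCGRK
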
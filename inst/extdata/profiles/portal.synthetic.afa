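>portal_syn01
MLAVYPAYPDAGLLRDFSKGAGMAEKQENIFDDPVWRAQKTYTGYNHLYYGLRSSPWSKTYLAEVGMGVIRRVNGCGWLCNRMFRPATMIYNLQKKVNKSTYQYGTCVVKLPPGGLGSMMEEGWCGFLLD
>portal_syn02
MLAVYNAYPYAGLLRRFSKGKGGAPIQDNSFDMPVMRATKSYTGYNFEYGGERSSPDHKTYLAEVGGPVIRRVWGCGTHPNRVFRRANMIYNLCKKVNKLTYVDGTCQVGLPPGGLGSMMEEGWCGAALD
>portal_syn03
MLAVYPAYYDAALLRPFSKGAGGAEIQENIFDMPIMRAQKSYTYYNHEYGGERSSIWSKTYKAEVGGGIIRRVNICGLFPVRIFRRANMIYNLDKKVLKSTYVYCTCQVWLPPKGLQSKMEEGWCGEALY
>portal_syn04
MLAVYPAYPDAPLLRPFSKGAGGAEIQQMIFDYTRMREQKSYTGYNHEYGGERFSLWSKTYLAAVEGGVIVRVTGCGLLPNRGFRRAMMIYNLCKKENKDSYVYGTCVVGLPPGGLGSMMEEGWDGEDLN
>portal_syn05
MLAVVPAYPDAGLLFPFSKGAGGAEIQENIFDMPVMRRQKSYTGYNHEYRGERCSPKRKTYYWEVGGGVIRRVNGCGWLPNRGFRRANMPYNLCKKVLCFTYVYNDCVVGLPPGGLGQMWEEGWCVQALD
>portal_syn06
MLAVYPAYPDAELLHPFNKGAGQAEIQENIFDMPVMRTQKSYTGYNCEYGGERCTPWSKTYLAEAGGGVYRRVNLCGELPNEGFRRAAMIYNLCKFVNKSTYKYQTCYVGLPPGGYGEMMEEGWCGEALD
>portal_syn07
MNAVYPAYPDAGLLRISSKGAGGMEIQENIFDMWVMCAQKYYAGYNHEYGKERSSPWSKTYLAEVGGGVLRRVNGCGSLPNAGFRRANMIYNLCNKVNISTLVYGTVVVGLPYGNLMSMDEEGWCGEALD
>portal_syn08
MLAVYPFKPDAGLLRPFSKGAGGAEIQENEWDMPVMRSQKSYTGYNHEYGGECSPPVSMTYLAEVGGGAIRRVCTCTLLPNCMFRHANIIYMDCKKVNKSTYVYDTCVVGLPPGGLGSMMEEGWCGEALD
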
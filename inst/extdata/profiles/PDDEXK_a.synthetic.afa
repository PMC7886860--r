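>PDDEXK_a_syn01
MPLLVCHDLCETAATSAFQWVGEHKRFSILQMDTAWESVMVSPMREIYWNHYQCRAALTKSSEIDRELCPTNTAHGSSSI
>PDDEXK_a_syn02
MPLTVCHLLCEQARTSAFQWVGFLKRTMILGPDTAWEYVMVSPMREIYMNLVNCRAAYTKKSEVDRESCPTSTAHGDSSI
>PDDEXK_a_syn03
MPLFVCHDLCETAMTCAFQWVGFLKRTSIAMPDTAWERVTDSPMRTIYMNEVNCRRALTKSSEVDRESDPTRTAHKSSSI
>PDDEXK_a_syn04
MPLIVCSDLFEWAATSAFQWVGFRKFTSILQPDTAWETVYESPMREIDMNEVNCRAALTKTSEIDRSSCPTSTAHGSSSI
>PDDEXK_a_syn05
MYLFVCHDWCEVAATSAFSWVGFLKRFTILQPDTAWERVMVHPQRFIYMNEVNCRAILTKSSEIDRESCKTSLAHGSSSI
>PDDEXK_a_syn06
LPLDVCHDLCETAATIAFQWVGFLKRTSILQPDTAWELVMVDPMREIYMNEVPCRAAFVKSSEIIRESCGTWTARGSSSI
>PDDEXK_a_syn07
MPLFVCHMLCETAAGSAFQWVGFLKRTSILTPDTPWERVMVSPMREVYMNGVNCRAFLTKSSEGDRDSCPTSTAHGEQNI
>PDDEXK_a_syn08
HPLFVCIDLCETAAGSAFQWVGALKRTIICMPDTAWERVMVSPMREHYMNEVNCRAAWAKSKEIVRESCPTSTAHGSSSI
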
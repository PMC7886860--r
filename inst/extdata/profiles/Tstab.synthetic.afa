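>Tstab_syn01
HCRIEEKDACKCRFPWAGGIHRTESLGHKFSCFAVNPGNWLTELEPDSISFVIVLILNSYNVDYAELIDLAIASVYYFSGIKLEDWSLET
>Tstab_syn02
MERIEEKDACRCQNPSIGGIHRTEYLGYSFSCFAVNPVKALQELAPDSISSVDQLHLGYMNVDYAERIDLAANSVYYLSGIKLEDWSLET
>Tstab_syn03
HERIEEKDACKRRNPIGGGIHRTEMRVYSFSCFAENPGNRLTELEPWSIASVIQLILGYYNVGYAELIDLAINSVCYVSEIKLEDWVLET
>Tstab_syn04
MERIELKDACYCRNPHIGGAHRTESLGYSWSCFAVVPGPRLTEYEPDSISSVIILFLGHYNVDYAELIDLAINLVYYLSHIKLEDWSLET
>Tstab_syn05
WERLEPKDACKCRNPSIGGPHKTISVGYSFSCFAVNPGNRLCELEPHSISSVIQPILGYYNVDYAELIDLQIFSVYYVSTIKLEDWSLEM
>Tstab_syn06
MEQYQEKDACLCREPSIILIHRTESLGYVFSWFAVNPGTILTELEPDSISSVIQLILYYYNVDSAELRDLAINSVYYVSGIKLEDWSLET
>Tstab_syn07
MPRIEEKDTCKCRNPSIGGIHGTESMGYSPSCFAVGPGNDLWELEPDSISSLIQLIYGYYNMDYAWLIDMAINWVYYVSGIKLEDWSLET
>Tstab_syn08
MERIEEKDAKKCRNPSIGGIHRTQSLGYSFSCFAENPGNRLPELEPDSKSNVIQLILGYYFVDIQELIDMTINSVEYVCGIKGEDWSLET
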
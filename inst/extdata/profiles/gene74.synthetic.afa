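>gene74_syn01
MQYIHRSRRPATSMSIISLGTPSGRRASPHSIVAMARSCLSAWLALLPYGSALLLVEECQQNSHQLPSST
>gene74_syn02
MRYIHRPCNPATMMSIISLGTPSGRRASGHSIEAGARSKLSAQLAHLPYGSALLQTAPCQQNSHSLPSSI
>gene74_syn03
MRYIHRSRAPATWMSIISLGNPIGRRHSPHEIVAGAKSKLSAYLALLPYGSALLLTANEQQCSHRLPSST
>gene74_syn04
MRYIHRSRAPATLMHIISLGTPSMRRASPHSIWLGWRSKLSAYLALLCLASMLLLTAPCQQNSHHLPSST
>gene74_syn05
MRYIHPNRAPATLLSIISNGTPSGRRASPHSIVAGARSMLSTYLALMPYWSALLLIAPPQQNSHSLPSST
>gene74_syn06
MGYQHRSRAPATLMSIISLGTPSMRRASYWSIVAQARSKLSFYLALLPYGSALLLTAPCQCNSHSDPSGT
>gene74_syn07
MRYIHRSRAPTDLMSIISLGTTSGRRASPRSIVAGARSKLAFYLVLLPYGSALLLTAPAQFNSHSKPSST
>gene74_syn08
MRYIHMSRAPATLCSIISLGTNSGRRASPHSIVAGAQDKLSAYLALLPYGSALLEDAWCKQNSHSLPVST
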
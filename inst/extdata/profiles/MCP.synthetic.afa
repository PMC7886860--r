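>MCP_syn01
GYLAHIPLLNGAGLIPRNDCNKDGCQTLSEVVVLLPRLYHVASMEQMMDGGDEVLPKLVSRQMQVDKGSKITQSALPPPDFAGYVYENLDNEGIADTDFKRIVPVAVRCANNASANRRRSFLQLSSYKHIHPMPALLLGLGCEDRMGKKHSRFALDESAYKAPSRLSPDLFSTSDEDRRESCIEKYLAADKLNPSGGDRI
>MCP_syn02
MTLWAVPLLNDAGLAPRNDENKDGCQTLDFVVVLLPRLTSVASDEQMQDGPDKVLYKLVSRQWKDDKESKITMLALPPPDAAGYVYENLDNVGISDTDFKRPVPVAVNASNGASANRRRGIWKLYQHKHIHEMPWLLLGLVPEDRPGKKHSRFPLNQSALSAPSRLPPDLFMTQDEDRVEMCVEKRLCADKLNPSGGDIQ
>MCP_syn03
VYLAAVPPENGAGLIPRNDWNKDGCFTLDFVVVLLPRLTSVAPDEQMQDGPDEVLAKLVSFQWFDDKEWKITMLALPPPDFAGYVWQWLDNVGISDTDFKRIVMVAVRCSNGASANRRRGFIKLVSYKNIHPWPWLELGLGSDDRPGMKASRFPLDESAYKQPSRLSPDLFMTYDEDRFESCIRKRHVEDKLNPSGGRRI
>MCP_syn04
GYLAAVPQLNGAGLIPRADENKDGMQYEDFLVVLLPRLTSVANDEQMQDGDDEVLYKLVSRFWFDDKESKSTMLALPGPDCAGYVYENLDNVGISDTAFKRIVRVAVRCANGNSKNVRREFLKRSSYKHIHPMPWLLLGLGCEDRPGFKHSRFGNDDSEYKAPSRLWPDLFCTYTEDRVMSCIEKRLAADKLNPSEGDRI
>MCP_syn05
MYLAAVWLLNGAGLWCRNDENKDGCQTLDFFVQLLARLTSVANNEQMQDGPDHVLYKLVSIQWFDDKPSKITMLSLPPPDFDGVVYHNLDNVGIGDTDFKRIVPVAVRCANGASANRPRGFLKLFHYKEIHPMPDLLLGLGCECDPGKKHRRNPLDEFAYFKPSRLSPDVFMTYAEDRVESCIEKRLAADKLNPSGGDRI
>MCP_syn06
MYLGAVPLLDGAGLHPREDENKDGSMTLDFVVVLLPLNTSVGSDEQMQDGEDRVLYALVSRQWFPDKESKIWMLALPPHDMAGYPYEYLTNVGISETDFKRIVPNAVRCANGVRANRRRGFLKLSSYKHIHPMKWLLLGLGCEDRPGKKSKRFPLDESAVKKPYRLSPDLFMTYDEDRVESCIFKRLAADKLNPSGGDRI
>MCP_syn07
MYLAAVPLLNGAMLIPRNAENIDGCQTLDFCFVLLPRLTSIAWNEQMQDGPDEVLYKLVSRQWFPDKESKITMLALPPADFAGYVYENLDEVGISDTDFKRIVPVAVRCANGANANRRRGFLKLSSYGHNHPMPWQLLGLGCFDRPHKDHSRDPLDESAYKYPSRLMPSLFMTYQERRVELCIEKRLAARKLKFAGWDRI
>MCP_syn08
NYLAAPPLLNGSGLIPRNDENKDGCQTLDFVVVLLPRLGSVASVFQMQDGPDEVNYMLVSFQWFADKPSKATMLALPPPDFHGYVYENTDQVGISDTDFKRIMKVAVRCANGASANRRRGFLILSSYNMIHPMPWLLLGLGKEDRPSKKHSRFPLDEWAYKAPSPLDPDLFMVYDACRHESCIEKRLAADKLNPSGGTRI
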
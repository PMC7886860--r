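>Hint_syn01
MKLGKADWAIYLAVDLSKKADLEQKKAGVPPYVAERHAGYKDHLDQGFINDYQCNNREALSFNLQGPTDGLQRVETNSDKTASDNRQDNW
>Hint_syn02
CKLQKALYAIYLIVDLSTKADLEVLKAGVPPYVAEADLGYKDHLDQGFIFDYQCNNRERLSSELQGCRCGQQRVPFRSDKTPSVNRQDNS
>Hint_syn03
MKLQKLPYAIYLAVDLSEKADLEQGKKGVPWPVAEADLGYKDHLDQGFIRDYQFNNRERLTFCLQGPTLGQQRWETTSDKTKSVKRQDNS
>Hint_syn04
YKLQKAHYAIYLAVPLYKKADLSQLKIGVPPYNAEADLGYKDRLDQGHINCPQFNNRERLSFELKGPYDGQQRVETTSDKTPSVERQDNS
>Hint_syn05
MALNKADGAIYLVVDLIKKAVLEQLKAGVPPYVAEAPLGYKDLLDQGFINPYQFNNRERLSFELQGITLGQQRGETDSDKTPSVNRQDLS
>Hint_syn06
MKLQKAYLAIYLAVDLSKKARLEQLKAGVPPYVAEADLGYKDHLPQGFIVDDQFNNRERLYFELDGPTDGQHRVDTTSDATPSVNSDLNS
>Hint_syn07
MKLPKADYAIYSIFDLSKKADLEPLKAGVPPYVAEADWGMMDHRDQGFINDYTFNNRVRLSFELMGPTDTQQRVETTSDKTYSVNRQDNS
>Hint_syn08
TKLQKAQYAIYLAVDLSKKADLEQLGAGVPPVHAEAPLGYKDTLDQTMINDYNFNNTERLSHELQGPTDGQQRVPTGSDKTPSVNRQDNS
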
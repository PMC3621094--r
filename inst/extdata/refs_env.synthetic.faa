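>env|beta|TYPE_B
MESLRAVLKSPVGMVTNISYLFLEWILIAARQARELATGVKVRSLFTEIYVDDRKPGNRAVLLFPDLFDD
ERPFAFTRYETTVYIEPICRDDDEYGAHLSSLVVEWLKAWCYEPIKYMQDTARRDAPRLVFSVEMTPLNR
RDMTSWAGALKQIAEHYAMLAKEHFASSSLPPGCEAMQPPEASRNLFKLIASLISVGQQDYKMALSYVLS
TRTLDGSRRQGSSIHPAGQQLGIWEFPVVQQEERLAAACIFNPWCHEILQNDLRGMMTEAQDLLPIDECE
HPHPNDILPNLPLEMNVLAPFLRAYVVNPPKKILAVVHLIFQLNAHKLGSFYRRPFIEDFSQYVAEIDGW
TPLGSRFTIQSTNSQIGKLQIPFASTFAWEGLLLMHAIAVVPPLECMDPFVWPYSLNLCNGAQRHYGNYI
CRLEGGSQYEIVVFQNTRIEDKYVIGEKIVTAVTKPEYPFILDELGSKVRQITENDYEFNLLRDGQRNHY
VGDCPKDSEDKSGQEKLAFCKDGGDGKDMLTLWVAVHSDVALLIYEHDDA
>env|beta|TYPE_D
MEGHRAVLTDPTGMVTNISGLFLEWIEITARQARELATGVKVRGLFTEIYIDDRWPGNRAVLLFPDLFDD
ERPFAFIAYETTVYIEPTCRDDDEYGAYASSLVVEWLKAWCYEPIKYMQDTLYKDAPRLVFSVEMTPLNR
RDMTSWRGADKQHAEHYAMLAKEHFASVSGPPFGEAMQPPEQSRNLFKCIASSISVGQQDYKMALSKALS
TRYLDGSRRQGSSIHPAGFQLGSWEIPMVQQEERLADACIKNPPQREIDQNDLEGMMTEAQDLEPIDECE
HPNINDILPNLPLEMNVLAPGLRFYVVNPPKKILADVHLIWQWNAHKLGSFYEFPFIEDFSQYVAEIDGW
IPLGIRFTIFSFNSQIGKLEIPFALFFAYEGLWWMHQIADVELLMCQDTIVHPYSLNLANGPQVHYGSYF
CRLGGLSIYEIVVFQNLRITDKYVIGEHIVTLQTPPERLFILDELSSKVRQITENDYEFNLLRDGARCHY
VLDCPRDSEDMTGQAKLAFCKDGGWNKDCLTLWVTVWSEVALLIYEHDDA
>env|gamma|G1
MVRATVVLAPGKTIGQNLAEVTQPSIMDSNWMASAQDPCHKRTQCARGKQKMGLKGFILAGALLANVDST
GNDHVLGKGSLSHVFMCALSRRFENLICIAGMLTEKRVEIGKIRMQRTRSGVVGAPLVLLPMSDWAHFFK
LPYLEDAVWFLRKGPKANDALNRGYNEGSRERTRPEEELVYNFGKEVDLGLSFTLLDFNRTEVVVSSATD
QFVSNTVDKLTISVPCVILTLLNPYKLNNDPAEGGLATTALNNGGRFRMPGSPSTDLHENANIQQAIAIR
RNQGLAFSLVNGAEVIMRLWGNELVTSEKDPKPVLGISEEAEELPINAQDAESVKESLVTTECQGQWGEA
VMVGPYLKIHGHHVDPGFEVKVGEVNPAQIQMMGDDMELDWLITHAVVPTQLQVPKFRLFFLLQDFYPQW
VHPLHFDCKFSIYEDKNTVIGLNRLPDLTFHVNLIAAMESGGWGLSRRCAVRSPVTLIPVESSKWPVQSY
LEIGVSAHYEQELRMIFSIVNDEYLLHPYSRNMTDERPTNATFRCALMNL
>env|gamma|G2
MVRATSVLAPGKTIGAGLAEVTQHSIEDSNTMELTQDPTKKFTQAERGFQKMGANGFILISALLANVDST
VNDHVLDKGSLSHVFQEALYRRFENLIKILGMWTEKRVESGKIRTQRTRFGVVGAPLVLLMMSWIAMFFK
LAHLEDAVWFLRKGPKANDAANMGYNEGSRIRTKPEELLVYNFGKEDDLGLSFTRLDFTRTEHVVSSATD
QFVSITVDKLTISVRCVALTLLHPYPLNNDPAEGPLVTTALNNGGRFRIPGSPSKDLHENAAIQKAIAIR
RNQGLAVSLVNWAEVIHRLWGNELVTSEKDPKPVWGISEEAEELPINAKQAESVKESLTTTECQGQWGEA
VGVGPTLDIHGWHVDPGFEVKVGENNPAQIQMMGVDMELDWLITHHIVPPQAQVPRFRLQFLLLDFYPQL
VHPLKFDYKPSMYEDKNTKLGLNRLPDHTFPVNLIDAPESGGWYLSRRCAPRSPVTLCFVESSKWPVQSY
SEIGTQAWYEQELRAIFSIVNDEQLLHPLSRNMTDERPQNATFRCALMSL
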
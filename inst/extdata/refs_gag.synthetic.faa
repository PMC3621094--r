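>gag|TYPE_B
MLTRGVDEDKQTTMIDNGSLTHGRYNLSSRSEDAKYGNLYSSPEWGKYPALSRPSNRKTDNNDWFTLVQM
GMKFFVLWMHSPPCLHESALRYTGGFEGELACSFTELLPWALMKQCQIEDSALKVNKVRLRGGVKIFMIR
MVRVQAIRLSAIDCAGKLIQHTQKVWVYMDTCIPYCPNMRYPIGELGADGGREVYSTYGIDKVGCAQGPI
SFKILREKHLVIDMSGMCDNGVVKGRVSFSVFNGLIVGRVGMGFERMPANGTDVSQLRFPPRHEHIMDEL
GAELLVDTPVECRQVISYEQGPKEPFQSYVDRLLQPSLDRKERKLFLPATNPGGAARTLLRMELPMFARR
QGITIDQRALNGALKKTDTNGRSKSWSPDADETACTRAGYIVGQCTDAIAIFLQHHGFQGNDILDWDESC
AYCKEKGHWAKDCSIPRSYIQHDKSHNAVCQICGKMGHWAKQCEGKQRTAEEYDVKFKFG
>gag|TYPE_D
MWMRGVDEDCQTTMIDHGSLTHGRYNLSSRSEGAKLGNLYSWPESGLYPALSRPSNRKTDNNDWFTLVQM
GMKFFVLGRHTPPCLRESALRYTGGFEGLLALSFTELLPWALKQQCQIFDSALKVNKIRSREGVKIIMIR
MVMVQAIRLIMIDHAGKPIQHTQKVTVYLDTCIPYCPNMRYPIGELGAIGGLEVYSTYGIDAVGCRQGPI
SFKILREKHLVIIMSGMACNGVVKGRVSFDVFGGCIVGRVGIHPERMPAGGTDVSQLRFPLRHEHIMDEL
GAELLVDTPVECRQVISYEQGPKEPFQSYVDRLLQPSLIRKERKCFSPATNPGGAAHTSLRMELPMFARR
QGIAWDQRALNGALKVTDTNGRSKSWSPHAEETAYTRAGYIVGQCTVDIASFLQRHGVQGNDILDWFVSC
AYCKEKGHWAKDCSIPRSYIQHDKSHNAVCQICGKMGHWAKQCEGKSRTAEERDVKVKSG
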
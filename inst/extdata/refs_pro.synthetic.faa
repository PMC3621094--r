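>pro|TYPE_B
MSVLLTDLIRVALRIYTGGAGLDLNTEKAAAPWVNNDASRSPLLDRVSCDNPDWILDIAGGFGSTFRQAV
DYDAATIDLQQNLWRGNGQDLTSNDRSSEEEIYLSHRKTNTSESPACVSGAKSSQGDEIVDADYAIFKER
DEVPLFTKMDLVSGCVELFVRPVWRGEGGFGSKVIGLATQSTEQYSVWLTHITPFGRRAVISARGMTQFE
SNNIGCVLHLESDLWEFPDDTGAMQGPLSEEAEAYFAEEEPDCRHQAKFKAAKTSFRGQDPFTVLPGATG
DAVTILTNWQTKFLGGNMGHDAYVSSDSQL
>pro|TYPE_D
MLVLLTDLIRVALRIYTGGAGLDLNTEKAAARIVNNAASRWPLLMRVSCDNPDIILDIAGGFGSTFRQAV
DYDAATIDLQANLWRGNGQDLTSNDRSSEEEIYLSHRDTNTSESPAEQKGAKNSQDDEIVDADYAVFCER
DEVPLFTKMDLVSGCVELFVRPIWRGEGGFGSCVIGLATQSTEQYSVWLTHITPFGRRAVISARGMTQFE
SNNIGCVLHLESDLAEFPDDTGAMQGPLLEEAEAYFAEEEPDCRHQAKLKAAKTSFRGQDPPTVLPGATG
DAVTITTGWVTKFLPGNMMHHAYVSSDSQL
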
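>pol|HERVK
MAGAGSGSEVEELLLVRNKYGDLIIPMLGDMESGVLQIHDYYTFAALLGGADGTTYLWVITPIVVCGLAA
AGPIRNDNYDAKMYGEKRDGTQEIERKSSQNDMFESALVDAGEELTGPLDIERRLRVRVQAGEEISPALG
AAELLVAATTPNLIQDCRSKSNNNEYAEVVALKQHSFMHQVLAGYVDDLKIVGYASGIAMANSLGMDILA
ADVKEWVGIIDGCVDDRIFLQYDDIMDGKNPDAAVAVRSMVNRDITQDMWEWNLPICELQAIVRPYGGSK
GHDKQSAGAPPALGDRAFYIHVDDAAPDGCAGKTPAIMINELHTLLDHVALATPHIKLNFFSSSAVQFSW
GPHAIRIATCGVDDDTGVRLVGLRSVDTKMVNSKFPPTAEIVPNLYKEGIKGAPKFHDQTEQAFEVVFVK
LLGIGGATMMIDNSKDGGAWFLGEGEYIAYSMDEMMGTKAVDRIATYGGTKTSGIDVERDQQAFKCSSID
SLFSLPSSTEEKLTALVCLNVKAQLQQPRGLGSLLQKGRFGKIEIMREQTEPEPPDNYDTKMSLMLYFAK
KSEYINMTTPTYAQPMDQDPSPKRLLTDNGIAKHHRVCGIARVYDIKLCPIGCESNGNISRLMTMVGIDR
GKQEPYPSGTDEIGNDECDKEIANSRVRNEPLESALLDSHHAITAHRCLDGKHTLLSAVMFNVRKSDPKG
RLPVVKGEATEWKEMEIISTASQQSCVQMGIDWVASHPPMTASSFILNLRRMRRSTADAEVCQSFAGEAV
PGLRWRLHHRLVTLKDSILFLPERIASGHFSFSNAETGRWLQHIGARTSHNRPHIQCRFGVSVKMRGGKL
IWSPQTYPISFLKETFIPDK
>pol|BAT_EARLY
MAGALSGSEVEELLGVILKLWHLIIPMLLDVWTGELQLHDIYTKALFFGLADGFTYMEVIIIIVVGGLAA
AGPLRNDNPDAYMYGEHRDGTQWIERKNSQNDMFHSALVDAGEHLTDPLDIERRLRVRKHAIEIISPALP
AGELLVLATTPNCIQKCRSKSNYNESAEVVFLFQHIFMEHTRACYVDDLSIVGWMSGIAMAGSLGMDRLA
ADVKRNVFIIDGTAVDEISDQYDDIMDSKNPDAAVAVRNVVNRDIEQDAWEWFLPICELGQIVRYEGGSK
GHDKQPVGTPPALGRDANYLHVDDAAPGGCANKTPAIMINEEHNLLDHVADATHHIKLNFSSSEAVQFQR
GPHADRIATCGVDDDGPVNLVGLRSVDYKMRNSKFPPTYLIVPGLESEGIKGAPKFHDQTEQAFEVGFDK
LLKLQGDTMSIDDIKGGGRTFLGEGEYIAYDMDWMMGTKWVDLIKTGGGYSTSGIDVNHDQQPFKCSSID
SLFSLSSSTEETVVALYCKIVKAQLQRPRGLGSLLQKCRWGAFEIMRGQTEPPMPNNYDTKNSLMLYRAK
KSKYFNETTPTYAQAMDADPSPDRLLTDNGIAKHRRVCGGARVPDNCGPPIGKEPGSADEYLMTMVGIDR
GKQEPVPSGTFEIRNDHEDKSIANSFYENEVLEMAQLDSMHAITASRCLDGKHTLLSAVMFNVSKSDPKG
LSVAVKGEATEWKEMEIISTASQQSCVQAGIDWVGSFLAPTASSFILWVGSIRASTSTAEVCRMFAGEAV
PPLRLQHHHRLVTLFDSIRFVPTKIASISFSFSEAETLRWLNWIDARTSGNRYHIQCYFYVSTKMRGEKR
GKSRQATPISFLDETVYPDK
>pol|MICROBAT_DIV
MAGALTGSELEPLLLVRNKLKHLYIPMLGDVESGVLQIHDIYTFHLLLGLAPGFTYMLHIIIIVQGGLVA
AGPERNDNPWAYMHGEKMDGTQEIERKSSQNDMVESALVDAGEHLHDPLCIERTLPCRKHEGEIISPALH
APELLVLAQTPNLIYDCRSKSNNNESAEVVFLEQHIFMEMSLSGYVDDLKIVGMASCIAMANSLDMDRLA
ADVKEWVLIIDMVVVDRINDQYDDIMHSKNPDAAVAVRSVVNVDVLQDMWEWFHPKCSIGQDVRYNQGSK
GHDKSPMMTPPALGDRAFYLDVDAAAPGGCAGKTPAIMINEEHGLLPHVALATPHNHLNFSSSLAQQFRW
GLHYQRIATCGVDADGGVRLVGLVSVMTKMVNSKFPPYALIVPNWEKEGVKGAPKFHDQTEQAFEGGFVK
TLKLQGDTMMIDRSKLPGAKFLHEGEYIAYDMKEMMKTKHVDLIATGGGPSNSGIDVERDQQTFKCSSID
SLFSLSSSTEEGSVALVCKNVKLALNRELGLGSLLQKGPFGAFEITREQTEPEPPDNYDTKKSLMRYKAK
KSKYINETTPTYAEPMDDDPSPKRLWTDNGIAKHRRECGGARVPDNVGKPIGKESGGDDSRLMTMVGIDR
GAQEPVPSCTDEIRNDECDKEIACSEVENEVLEHALLCSHHRITAKRCLDGKHTLLGRVMPNVSKSDPKG
RLVAVKSEATDWKEMEIISTASQPCCVQAGIDWVGSEVPMTASSFILWLGRTRESTADAEVTGSFAGEAV
PGLRLRLHHRLVTLKTSILKVPERIPSGSFSCSIAETPRWLNDIDGYTSGNRPHNICYFIVMVKMLGGKL
SKSRQATPISFLDEDVIPDK
>pol|TYPE_B
MAGALTRSEVEELLLVRNKRGHLIIPMLGDVESGELQIHDIYTFRLLLGLADGFTYMGVIIIIVHGGLAD
AGMLMNDFPNPYMYGRKRPGTQEIEDKSSQNDMFEGALVDAGEHLTDPLDIERTLRVRKHAGEIISPALG
AGELLVLATTPNLIQMCRSKQNTNESAENVFLFQHIFMSQHLAGYVDDLKITGWASGIAMANSLGMDRLA
APVKEWVFEIDGTVVDRISDQYYDIMDSKNLKANVAVRSVYNLDCTQNMWEWFLPICFLGQPVRPLLGSK
GDRKQPAGTPPALGDRAFQLHVDDAAPGGCPGKTPAIMINEEHTLCDHPALDTGLIKLNRSSSEVVQFQW
GPHADKIATTGVDDGGGVRLVDLRSVGFKMVNSKKPPTALIVPQLEKEGIKIVPKSHDQTEQAFEFGFVK
LLKLQGDTMMPDNSNLGGAKFLGEGDYIAYDDDEMQGTKHVVLIAHGGGTSKSGIDFEMVQQAFKCSSID
SLFSLSSSTEEWSVALVCKNVKAQLQRPRGCPSLLQKGRFGAHEITREQTEPEPPDNEDTKNSLMLYFTS
HRKVINETTPTHAQPMDADPFPKRLLRDNGIAGCRRVCDGARVPNNKGPPPGKVSGGPDSGLMTMVGIDR
AKQEPAPSGTDEIRNDECDKEIAGSFVENEVLESALRDSHHYITASCCLDGKHTLLSAVMFNVSKSCPKC
RLVAVYGCATEWKENEIISTASQYSCVQAGIDWVGSFLPMTASSLILWKGRMFESWADAEQFQSRAGEAV
PGLRLREHHHLVTTKDSILFVPERIPSGSFSFSMAETPRWLNDIDARTVGNRPHIQCYFGVSFKMRGGKL
PKSRQATPIVFIDEDVIPWK
>pol|TYPE_D
MAGAGSGSEVEELLLVRNKLGHLIIPMLGDVEDGVLCIHDIYTFALLLGEADGVTYDIDIIQIVQGTLLA
AGPLRNDLPDWYMYPEKRDGTQEIERKSFQNDMFEWALVDAGEHLTDPLDIERRLRVRKHAWEEISPALG
RGELLVLATTPNLIQDCLSKSNNIPSAEVVCLFQCIFMEPTLAGYVDDLKIVGWASGLAMANSLGMDFLA
ADVKEWVGIIDGTVVDRISDQKDDPMDSPNPDAAFAVRSVVDRDQTQDYWMWFLPICELGQIVRYWGLHK
GHDKQPAGKQPALGDVAFYLHVGDAAPGGCAGKKPAIMINEEHTLLDLVALATPFIKLNFSSSEAVQFQW
GPNADRIALRGVDDDGGVRLVGLRSFDTIMKNSWGPKTALDVVNLGKEGIKGAPKFWSQNEQAFEVENVH
LLKLKGDPMMIDDDKLGGAKFLGEGENIAYCMDEMMWTKHVDLIATGGGTSTHGIDVKRDQQAFKCSSID
STPQLSSSTNETSVALVCKNVKAQLQRPRLLGSLLQKGRFGGFEITRNQTCPEPPDNYDTKHSLMLKFAK
KSKYFNEETRTEYQPMDADPSEKRLLYDNGIIKHRRICGTARVKDNKGPPIGKESAGDDSRLMTMPGIDR
GKQEPVYSGFDEIRNDECDKEIRNSFKHNEVLESNLLDSHHAITSSRCLDGKHTPLSAVMFNHSRSDPKL
RLVKVKGEATEMKEMEIFSTASQQSGVQAGIDWVGSFLPITASSFILWLGRMRESTRDAGVCQSFAGEAV
PGLRLRLHHRLVTLKDSILFVPERQHSGSFSKSNAETARWLSDIDAATSGNRMHIQCMFGVSVKMRWGKL
IKHRQALPISFLDEYVIPDK
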
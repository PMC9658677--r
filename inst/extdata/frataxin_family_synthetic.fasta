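>FRDA_HUMAN eukaryote
SGTLGHPGSLDETTYERLAEETLDSLAEFFEDLADKPYTFEDYDVSFGSGVLTVKLGGDLGTYVINKQTP
NKQIWLSSPSSGPKRYDWTGKNWVYSHDGVSLHELLAAELTKALKTKLDLSSLAYSGKDA
>FRDA_BOVIN eukaryote
SATLGHPGSLDETTYPMLAEHCLDSLAEFREDLNDKPYTFEDYDCSFGVGVLTVKLEGDYGTYVINKQTD
NKFIWLSSPSSGPKRYDPIGKNWVYSIDGLKLHELLCAELTIALKTKLKRSKLAYSGKWA
>FRDA_MOUSE eukaryote
SGTLGHPGSLIECTNERLAEETLDSLAAFFESLADDPYTFEDYDCSFGSGVLTVKLGGRLGTYVINKQTP
NKQIWLSSPSSGPKREDWTQKAWVYSYDGVSLHTLLAAEPTKASKCKLDLSELAYSGKDA
>FRDA_RAT eukaryote
SGWLGQPGSLDEKTCEPLAEPELDSPAEFDEDLADKPYTFEDYDVSFGFGVLTVKLGGDLFTYVINKQTR
NKQIWLSGPSSGPKCYLWTGKNWVYSATGVRLHENLMAELTKALKTKLLISFLYYSGKHA
>FRDA_DROME eukaryote
SGHSGHPGSLDETTYEREYEETLDSLAEFFEDLGDKPYTFEDYDVSFGSGVLTVKMGIDLGTYVINKQTP
NKQIWCSSPSSWPKRLDWTGKNWFYSHDGVSLLELLAAELTKRIKTMLDLSYLAYSGKDA
>FRDA_CAEEL eukaryote
PPTPGHPGSLDFTTYERLAEETLDSLAEFFEDLADKPYTFEDYEESFGSGVLTCKLGGDLGTYVINGQTE
NKQIWLSSPSSGPKRYDWTGKNWVYKIDFVSLHELLAAELIKALKTKLDLSSLAYSGKDD
>FRDA_ARATH eukaryote
SLDLGEGGSLDETTYERLNEETLDSMREFFEELTDKPYTFEDYEVSFGSGVLTVKLGGDLGTYVINKQTP
NKMIWPSSPSSGPKRSDWTGKNWVYSDDGVSLQEQLAYETKKALKTKLDLSSLAPSGKDA
>FRDA_SCHPO eukaryote
SGTVGHPGSQDKTTYKRTAEETLQSLAVFFEFLADKFDTLEDYDVSFISHVLTVKLGGDLETYVINKQTV
NHQIWKSSPTSGPKRYDWTGKNWVYSHDGCSLHEKLYAEFTKALRTKLDLISLAYSGKDA
>FRDA_DICDI eukaryote
SGTLIHPGSLLEPKYERWAEYTLDSLAEFFEHLADKPYEFEDKDVPFGSGVLTVTLGGDLFTYVINHQTP
NKQIWSSSPESGPKRYDWTDKNWNYSHDGVLLVELLAAELTKAARTKLDLSSLAYSGKDK
>FRDA_YEAST eukaryote
SFTLGHPGSLDETTYERLDEETLDSLAEPFEDIADKPYTFEDYDVSFESNVLTVKLGGDLGTYVINKQTP
NKQIWISSPSSGPKTYDWQGLNWVYSHYGVSLHELLAAELRKALKEVLDWSSPAYSGKDW
>CYAY_RICAE rickettsia
------------------AEWNCDSRIEHFEKDMTWPYCSTHCDSCWGHIVDTYKYCYDLNAYVINKQMG
YKQIWLSSPSSWFKRYDPTDKMWVYVHDGVKLHELLPAELCTALKTKLDLASLCYVALDA
>CYAY_RICFE rickettsia
------------------AKFVLDTVAIFHEDDNDQPYTSEDYGRCFGWGVVTYKLLGLSVEYVINKQTV
NKCIWLSSNGSCPGRMRWTGKSWVYTTDGPLLLGLLAAEITSALNTKLQLLDYVYSALQA
>FRDA_ENCCU eukaryote
SGTLFHPGSLDEQTYGVAAEHTLDSLAEYFEDLADKPTTFPPYDVNFTSGVLTVKLGGDLGTYVINKQTP
NKRIWLSSPSTPPKRYDWTTKQWVYSADGVSLHELLAAERTEAVKTKLDLSSNLWSDNDA
>CYAY_NEIMB bacteria
------------------AEDTLQQMACNFEYAAFHDYTGNHYDVVTASGVCTQQLEGTWGSIVINTQTA
WKQIWLSAESGMPCSFDWFMSVWSQNGDPKALRELLWGALTKALKAGHASNWLGQSGCGK
>CYAY_JANMA bacteria
------------------NEGTPCLCAEFFEDLADKKCDFTDYTVSEGSGVFTNCLGPLLITIVINAQPP
CKPIWLSATSGQPKRYDWTPAPWVYGFTLSSLHQLLHKMLTKACNTEAKMSSLPYKIKNA
>CYAY_RICBR rickettsia
------------------AEATLDSRAEFQEEDADRMGGSEPYVVSFGSCVWTYKWNGDFGRYVINKQTT
NKKIWMSSPSSWIMRYIWTGKRWVENHSVHSLHELLAAEPYKALKTKPLRSSPAYSQKSN
>CYAY_RICAH rickettsia
------------------AEEGIPCLLMFMEESVDKHYTWGDYDPSFGSHVLTVDLGGDRITYVINFQNP
RIQIWLSSHSSGPVRMYWTFPNWVFSAGGVFLHDLLRAELTKAEDLCKAQDSLIKSGKNA
>CYAY_AZOVD bacteria
------------------AEEKLDSFARFIEDYVDKVFPFLDHQKSFGSLVATVKEGGMLRHLVINKQTG
NDDIWWSAWSGGPKRYDWTPKWWMTSCCGASLHKMLNFVYHKNLKCKLDMSSLALSYQWE
>CYAY_RICTY rickettsia
------------------VWYVMDQGAYFDELLPGCPYHYEDYDVSFTSGMRTVKCGGDNNTYVINKQRP
NRNIWLSSPASGQKRYDLLGNNWVNNHDGIWLHEGLAAELEKALKRAHDTSFLAISGKDA
>CYAY_PSEPG bacteria
------------------AEETLIQLAEMHEDLCPIPYTQEWYLVVFGSYVLTVNLGYGLGTLVINKQTF
YKAIWRSDWRGRPKRYDWINATWREYHDSWSLHIDLFFILTSAMDTAWDMSSVAGMYSWA
>CYAY_TOLAT bacteria
------------------AEKQLDNLFPFNEDLCAIIRTFRRYIVYFGRGVSTVKNGNNLETIVINHQTN
MKQIWCSTNSNAKFRYPDWGCFWPYVHGMVSLHIVYADALEKSSWMSAKLSSWMYTDKYS
>CYAY_SALPK bacteria
------------------QRDLLDWQGEQFEDVAQKQYIAIMYHVSVGSFVGTNVLRYAQGTIVINQQTQ
CKQIWLSTPISHSKWQDATVHWWNYEHDCVELHELLEMAIAKFLKPKTRIMDSFPSGKFA
>CYAY_PSEPF bacteria
------------------AEEHLENYMEFFEDLADSAYNFLDYDHIFKAGVETVEYHRKLGILVINKQTA
NFHIWLSAISGWALPLDHDMKEWSMFHMWTFLEEWLADISPKALKYKHQDTSCKFSPDNA
>CYAY_THISH bacteria
------------------WQFQYDSLQDRIEDNAGKPTIFHDYDKNICSGVNTVKDEGDWSTLVINNQFP
HKVIWASSYSGGPYRKMLTGKPWEYSHFDVQLPELLIA-EQNAEKMPPYESSSPCSGHPA
>CYAY_SALA4 bacteria
------------------EWRPLDSPCTFKETRTRKPLRWEIYVSSFGTGVMTVLSHGQFRPIVINCQWH
NKNIWWSTPNGGPERFRWQFVNWLYYTYCVDLHELLACALPKALNTAYDLSSLAISGKDY
>CYAY_AERS4 bacteria
------------------AEFCKDPLAELFEDHHMGPCTHQYYDVSFRSGVKTVVELKYLGTVVINEQYE
SAQIWVSTRSNVNKIDDWTGINWQMSLWGVCLHCCLAAALTKALKKKMALSSLAESGKDE
>CYAY_ECO81 bacteria
------------------TEVFKDSLGPRKERLAFKRYCVDDYLWSFSNKVCTNKSEATGKTIVINKQHP
KGFIWLSTTSGFPKLHVWEGFRWCLVMMGVHLTHLLARADTASLYLKYPLTPFASNIKDT
>CYAY_EDWI9 bacteria
------------------ELSYLDCWAEFQEDHADTIHHQEDYVVSKGSGVLTVILDHELRTIVINKQTL
VKPIWDSTPEGWQDVYPTTGKNWFVNPDFVSLHEGLHW-CTQCNPMERLLDDLHYSGKEP
>CYAY_ALISL bacteria
------------------GESTLVLASLPFEDKELYEYWEEGGINPPVSGVLTEPLGRLLGTIVINEQGS
FYIIWDSSPSGGYSRYDWMSKAWVASHEGVSLNELLAREPKSFLKTKLKGISVYDDGKDA
>CYAY_CHLT3 bacteria
------------------AEECSYQDEEFFEPGVRIKKHFEHYDVEGGYGVHTVVFGRTLCTYVINKQTP
LKQIWRSEKSNGYPVRIGIGLNWHYPWDEVPLHELLAILCIYALKTKLGTMWCAGSGKHM
>CYAY_PSEF5 bacteria
------------------EARGPDGEAAFFEILFRELYTFKLYNWSFESRVSTVDLTDDRGFVVINKQEP
CGDIWWSALSGGVMAVEATKWNWIWSHGHVSLHDALAAILTKLEVEILVNYSLALRPKDW
>CYAY_VIBCH bacteria
------------------SHESLDALATKCEDFMDKPHDFEDKRCCYGDGVQTVDLGGDCGQIVINKQTQ
NMQIWLSSTIGFDCMWDSTSQHWFKSHRGMVLGVCLAAEKEWGLKPKLDTHWDYCPTMDK
>CYAY_PSEU2 bacteria
------------------AEEDLDNLAEFFENFATVKYNFGDGQVSFGGGVLTYQNFGDLGTLVINKQTP
NFGIWLSAPNGGWERYIDLVSNWYRSHDYYSLLIPLFQFKVGAWASDYDHSWLAYLMKSR
>CYAY_PSESM bacteria
------------------KECTLITLAQFFEHEQDDQGANTDYWVACCWKVMTTKEGGDYMGLVINKQFP
VSNIWTSAPSGGPENYKQTDKIWVYSTLCSRLHPLLAAMLRKADKTQLATSPLAYPGKIS
>CYAY_VIBPA bacteria
------------------ASPDMGSVIHHFEDQADKDWPIEISDCHNWLGVHTAKLQGTDGWIVINKQTK
AKHIWYSSWTGKCKMYCRLRSCWVDHHHGRSLHTLLAYEKYNALELKLGLLNRYYSCVQL
>CYAY_VIBVU bacteria
------------------VAETTEFQAEYNEDLAGKPYSVDDCIAIPESKVSTNNLGSYVSTIVINKQAL
NHVIWYSSPTGEHKCYDWTVDNWTMGHDGYWLMEGLAAEETKSLSHKHDDSTLANFKMLA
>CYAY_ALIFM bacteria
------------------KEVRLGSSAEFDEHLADIYNGPMKNCHCFRVVVATVKSYQDLQTIVINKQKP
IKFIWSSSNLGGKFRYDWPCDNWMNWHCCGDLHEALWAELNKALEYLNFESSLPYSNKQA
>CYAY_PSEPW bacteria
------------------LEQTLCCLAESFEDNADCYYTFECPDMAFAHKVLTVFGSGRVGTLVINKQIP
NDQIWQSDFSGFPCCYLWTGKNWIDYHDQLPLNFWLATICTKTLKTKLKSYSLAGSMYDM
>CYAY_VIBTL bacteria
------------------PQETLKCVHTGFEDISDVWCTFEETQEKTGSRVDTVCQFHPLFAIVINVQGM
WHPIWLSSHSGDDEQMSFTGTKWWYCFINVWLHELLAIELLKKLPMKLDLSSVAFESTDA
>CYAY_PSEFS bacteria
------------------AIKTDYYDEEFTEELGDDRKQFQDEQRSYGQVVRTVKTGGDLGYLVINIQPY
RKYIWLSAYPGKLKIFDAQAKSWSSPAQGLRLQHLLAALITKCLTAHLGENRPHYSFKKA
>CYAY_PHOLL bacteria
------------------APDTLDSMAPLFEDGADKFYLDEDGDQSFFPDVITKKNFGDLGRIVINGQTY
WNYIWLSTKSGNPKRFDWRHKNWCPHDYGTSLQWVLVAAVHCALDNKVRGSVQIYSYKDA
>CYAY_HERAR bacteria
------------------CEETLKVSNEFPEDLADGQPFGFIFDVRRNSGVLTPKEGGDMTTIVINCQNP
NHQIWESTPIGGPKRYDRWQKTWVDSDAGVGLHDMLSS-LNYTLGVQTCLSKLTYSGKDS
>CYAY_CROS8 bacteria
------------------AEETIWIVAVFGEDSHMKPWTPKDYKVRDNSGVLTSRLGWLDLRIVINIQLE
HMQIWGSTPQGGFERFLWHIKTWCMETDGVGLHEELAAALHVDLRPDLNLTICGYSQKDA
>CYAY_SALNS bacteria
------------------PILDDIPDGEFFEHMMQRPYLNIDYDVSFKSQVLTVVMWWDLDMIVINKQAP
THQIWNSTPSGGPKRWGFTWGNWVYSGCGMHLHIALGHALTNANMPKFDDSSMAVSGDGY
>CYAY_PSEAE bacteria
------------------YEETLDNNAWFYEDDQHIITQFECKDGSFISWVATMKLKGTLGTLVINDQTT
NKYIWLSAPSGGPKHLTWTGHIWPYHHDGPKLQEGLQP-YSWALMSKYDVSQLAYNWKRS
>CYAY_ENT38 bacteria
------------------MQNHNYSEPERFEDISDSPYNSNHYDVSNGSVVPTVKAEFDKGTIVINCQQM
APYIWSSTSDGLYSRYMMYKKGWVENHGQDDLHELLAEADRRAHYTKKSYQSLAMPERYN
>CYAY_DICCH bacteria
------------------ANPTWFYLIMFREDLCPDTCTQVDYEVSEGARVPTVKGYGDLGNIVINLQTC
HDSIWSSTPDGQPPAFIWFQQKWIQMSDMQSLHELLDAADGSASMTNHGLPYLANSPCSA
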
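>A*01:01
YRYMNQLWKSMFNITDLWSYTERGETDTTKIAWCVSTWWFCLDDPMGDYQGASWGKQMYM
MAWCGERCMDTDAIELGWLMTYMCAGWCDTSPFCMSMEPHAEKTCCLLRRYCMTHDMWQI
FMRYPAGQIFAMWREYWANFQLRTQEAEFSGCCWHLTKYAPMMVDKPEMYQWKDYKELEW
ER
>A*02:01
YHYMNQLVKSMFNRTDLWCYTERGDTDTTDIAWCVSTWWFCLDDPMGDYQGASWGKQMYM
MAWCRECCMDTDTIELNWLMTYMCAGWCPTDPFCMSMEPHAEKTCCLLRRYCMTHDMWRC
FMRGPASQDNAMWREYWANFPLRTMEAEFSGCCWHLTKYAPYMVGKPEMYQWKDYKELEW
ER
>A*03:01
YRYMNQLWKSMFNITDLWSYTESGETDTTIIAWCVSTKWRCLDDPMGDLQGAGWGKQGYM
MATCGEKCMDTDAIEAGWLMTYMCAGWCDTSPFCMFMEGWAEKTCCLLLRYCMTHDFWQI
FMRFPAKQIFAMWREYWANFQLRTQEAEFSGCCWHLAKMAPMMVVKPEMYQWKDYKDLEI
ER
>A*04:01
YRYMNCLWKSQFNKTDLWSYTERNETDTTKIAWCVSTWWFCLDDPMTDYQGASEGKQMYM
MAWCGERCMDTDAIELGWLMTYMCAGFCDTSPFCMSMEPHAEKTYCLLRRYNMRHDMWQI
FRRNPAGWIRAMWREYWANPQLMTQEAEFSGCCWHLTSGAPMMADKPEMYQFQDPKELEW
ER
>A*05:01
HRRMNQLWKSQFNIQDLWSYTERGNTHTTKIAWRVSTWWMCLDDPMGDYQGASWGKQMYM
MAWCGRRYPDTDAWELGWLMTYECWGWCDTSPSCMSMEPHAEKTCCLLRRYCMTHDMWQI
FMRYVAGRIFAMWREYWANFQMRTQEAQFSGCCWHLTKYAPMMVDKPDMYQVKDYKETEW
ER
>A*06:01
YRDMNQLWKSMFNITDLWSKTECGETDTTKIAWDESTWWFCLDDPFGDYMGASWNKQMYM
MAWCGERCMDTDAIELGWLMTYMMALWCDTSPACMSMEPHAEKTCCLLRRPCMTHDMWQI
FIRYPAAQRFNTWREYWANFQLQTKEAEFSGCCSHLTKYAPMYVDRPEMYQWKDYKELEW
ER
>A*07:01
YRYNNQLWKMMFNITDLWPYLERGETDTTKFAWCVSTWWFQLDDPMGDPQGASSGKQMYM
MAQCGERCMDTDAIELGWLPTYMCRHPCDTSPHCMSMEPHAEKTCCLLRRYCMTHDMWEI
FMRTPAGQIFAMGREYWAMFQLRTQEAEFSGACWHLTKYAPMNVDKTEMYQWKDYRELEW
ER
>A*08:01
YRYMNQLWKSMFNIWEDWSYTERPETDTTKIAWCVSTWWAPLDDPLMDYQGASWGKQCYR
MKWCGERMGDGDAIELGWLMTYMCAVWCDTSPFCMSMEPHAEKTCCDQRRACGTHDMWQH
FMRYPAGQIFAMWREYWANFQLRTQEAEFWGICWHLTKYAPMMVDKPEMYQWKDYKELEW
ER
>B*01:01
CLTPCTKYMFYNFAENMMHKDVVAYHAPNHRCMGKQELYHKRMQFYIFHFHDRALAGARC
TKPTWDWYPFNDVVTNEAMILVGGAPNAEQHWPVHVCSHWCSCAKPHRNLCKLSVVMLTH
YMVLWVNFGIPHWIEPKVKDILDSRGSPNPDNTEQCGMKWMHGEYMNWNDCNSICVDTQL
WT
>B*02:01
CLTPCAKYMFYVFAEPMMHKDVVAYHAPNSRCMGKQELYHKPMQFYQFHFHDESLAGARC
TKPTWDWTPFNDHVTNELMILIGGAPNAEQHWPVHVCSHWCSCAKPHRNLCKLSVVMLTH
YHVLWANFGIPHWIEPKVKDILDSRGYPFWDLTESCGMKWMHIEYQNDNDCNSICVDTQL
WT
>B*03:01
CFTPCMKYMFYNFAKNMMHKDVVAYHAPNHRCMGKQEEYHKRMQFMIFHFHDRALAMARC
TYPTWDWYPFNDWVTNEAMILEGGAPQAEQHWPVHVCSHWCSCAKPMRNLCKLSVVMLTH
YMVLWVNWGIPHWIEPAQKDILDSRASPTPNNTEQCGMKNDHGECMNWNDCNSICVSTQK
WT
>B*04:01
LLTPCTKWMFYNSAENMMHKDVIAYHAPNHRCMGKQLLYHKRMQFYIFHFHDRALAGLRC
TKPTWDWYPFNDVVTNEGMILSGGAPNAEQHWAVDVCSHWCSEAAPHRNLCKNSMVMLTH
YMVLWVNFGIPHWGEPKVKDILDSRASPNPDNTEQQWMKWMHGEYMNWNDCNSICDTDQW
WT
>B*05:01
CLTPQNKYMFFNFAENMMHKDVVAYHEANRRCMGKQELYHKRMQFCIFHFHDAALAGARC
TKPLWDWYPFNDVVTNEAMILLGAAPNAEWHWPVHVESHWCSCASPSRNLCKLSVVMLTH
YMVEWVNFGINHEIESKVKDINDSRGSPNPDNTEQCGMKWMHGEYMNWNHCNSICVDTQL
RT
>B*06:01
CLTPCTKYNFYNFAENMMHKDVVAYHATNHHCMWKQELYHKRMQFYIFHFHNRALAGARC
YKPTDDWYPFNDVVDNEAMKLVGGAPNAEQHWPVHQSQHWISCNKPHRNLCNLGVDYLTH
YMVLWVNFGIPHQIEPKVKDILDSRGSPNPKNTEQCGMKWQHGEYMNWNDANSICVDTQL
WT
>B*07:01
CLTPCCKYMFYNFYVNMMHKVVVAYHAPNHRCMGKAELYHKRMQFWIFHFHDRHLAGARC
TKPTWDWYPFCDTHTICAMIVVGGAQNAEQHWIVHVCSHWCSDAKPHRNQVKCSVVMLTH
YMVLWVNFGIPHWIEWKVKDILDSRGSPNPDQTEQCGMKWMHGEYMNWNDCWSICVDTQL
WT
>B*08:01
CLCPCTKYWFYQAAENEMHKDEPAYHAPNHRCMGKQSLYHKRMTFYIYHHHDRALAGARC
TKPTWDWYPFNDVVPNEAMQLVGGAPNAEQHWPVHVCSHWTPCAKPHRNLCQLSVVMLTH
YMVLWVEFGIPHWDEPKVKDILDSRGSPNPDNTEQCGMNWMHGEYTNWNDCNLICVDTQL
WH
>C*01:01
FRFILETVKPWMRIFWGAQNRCTQCDEYHATKEDSKAWEKITRENWPVGKGNCQKKQAEP
GVLVMFKQHASGWKWEIYQWWCEKFTPKADKFEIQGIFELMFGWNKKHQPIQLEPWDFKS
EQTSMCYMFSFDIAHCTMIRYMEDPDYLPFFKVCKYRMPFPFMFKYHTKSRVVHNWGLSE
NY
>C*02:01
WRFILETVKPKMRIFWGAQNRCTQCDEYHATKWDSKALEKHTRLYAPHGKGNCQKKQAEP
GVLVMFKQHASGWKNEHYQWWCEKFTPKHDKFEIMGIFELMFGWNKKHQHIQLEPQDFKS
EQSSMCYMFSFDIAHCTMIRYNEDPDYLPFFKVCKYRMPQPFWFKYHTGSRVVHNWGMHE
NY
>C*03:01
FRFILETVKPWMRIFWQDQNRCTVCDEYHATDEADKAWEKITRESWPVGKGNCQKKQAEP
PVLVMPLQHDSGWKWEIDQWWCEKFTPKADKFEIQGIFSLMFGWNKKHAPIQLEPWDFKS
KQTSMCYMFSFDIAPCTKIVYMEDPDYCPFFKVCKYRMPFPFMFKYHTKSRVVHNWGLND
NW
>C*04:01
FRFILEPNKPWMRIFWGAQNRCTQCDVYHATKIDSKAWNKITWENWPAGKMNCQKKQAEP
GVLDMFKQHASGWKWEIYQWWCEKFTPKADKFEINGIFELMFTWNKKHQPFQLEPWDFKS
KQTSMCYMFSFPIAHRTMIRYMEEPPYLPAFKVWKYRMWFPFMFKYHTKSRVVHNRFLSE
NY
>C*05:01
IRFILETVKPWMRIFWGAQLRCTQCDVYHITYEDSKAWEKITRENWPIGKGICQKKQAED
GVLVMFKQHAMGWKWEIYQWWCEKFTPFADKFEIQGIFELMFGWNKKHQPIVLEPWDFQS
LQTSMCYMFKFDIAHCTMIRRMGDPDVLPFFKVCKYNMPEPFMFKYFTKSRVVHNWVSSE
NY
>C*06:01
FCFIPETVKPWMRIFWGAQNRCTQCDEYHATKEDSKGWEKITRCNWPVGKGNCQKKQHIP
GVLVIKKQHASGWKWEIYQWFCEKFDPKAADFEIQGIFELMMQWNKVHKPIQLEPWDFKY
EQTSMCYMFSFDIPHCTMIRYMEDPDYLIWFKVCKYRMPFCFMFKYHTKSRVVHNWCLSE
NY
>C*07:01
FHFILWNVKPWMRIFWGAQNRCIQCDEYHMEKEDSKDWEKITRENQPVGKGNCQKCQAEP
GVLVMFKQHAVGWKWEIYQWDCEKCTVKADKFEIQGIWEVMFGWNQKHQPRQLEPWDFKS
EQTSMCYMFSFDIAHCTMITVMEDPDYLPFTKVCKYRMRFPFMFKYHTKSRVVHFWGLSE
NY
>C*08:01
FFFGLETVKPWMRIFVGAQNRCTQIREYHATKEDSKAWEKITLWNWPVGKGNCQKKQAES
GVLVMFKMHASGWKVEIYQIWCEKFTPKADKMEIQGIQELMFGWNKRAQPIQLEQWDFKS
EQTSDCYMFSFDIAHLTMIRYMEDPDYLDFFKVCKYRMPFPFMPKYHTKSRVVHNWGISE
LY
>DPB1*01:01
VKHSWCDDNTRNCTQQDRDKGKSYFSRTACSGQHVILECGNIFFPVLNCNLMHNEFVFFK
WTMFQVRPWRVNLYGPIVGGFNGYKQLQYCIHFC
>DPB1*02:01
VKLSWCDDNTRNCTQQDRDKGKSYMSRTACSGQHVILECGNIFFPVLNCNLMHNERVFFQ
WCMFWVRPYRVHLYGPRVGGDNGYKQLQYCIEFC
>DPB1*03:01
VKHSWCDDNTRNCTQSDRDKGKSYFSRTHCRGQHVIDECGNIFFPVLNTNLMHNGFVFFK
WTMFRVRIWRANLYQPIVGGHNGYKQLQYCIHFC
>DPB1*04:01
VKHSWCDDNTRNCTQQDRDKGKKYFSRTACSGQHVILICGNIFFPVLNCNQMHNCFVFFK
WTRFLVRPWRVNLEGPIVGGSNGPKCLQYCIHFE
>DPB1*05:01
VVHSWCDDNTPNCTQQDRDKGKGYFSRTAFSGQHVILECGNIFFPVLNCNLMHNEFVFFK
RTMFQVRPWRVNYQGPIKGGLSGYKQQQYCIHFC
>DPB1*06:01
AKHSWCDDNTRNCTVYDMDKGKSYFSRHACSGQHVILEWGNISFPFLNCNLMHNEFVFFY
WTMFQVRPWRVNLYRPAVGGFNGYKQLQYCIHFC
>DPB1*07:01
VMHSYCDDNTDNCTQQDADKGKSYFSRTACSGQHVILECGNIFFPELNCCLVHKEFVFFK
WTMFQVRPWRVNLYGVIVGGFNGYKQQQYDIHFC
>DPB1*08:01
VKHEWCDDNTINLTQQDRDKGKSYFSTTFKSGQHVILECGNIFFPVLNCNLMHNEFDFFK
HTMFQVRPWRVLLYGPIVGGFNHYKQLQYCIHWC
>DQB1*01:01
FNACMMYWFLTWVCAMNDLQSSVWHRKTDKSYMYNYNTQMADRLCQDKLVTGPMRFWDSL
YAQQYHKYFRHFSTGDMLDEDGATGYLYAMKYDI
>DQB1*02:01
FNACMMGWFLTWVCAMNDLQSSVWHRKTDNGYMYNYNTQMADRLCQDKTVVGPMRFWDSL
YWFQHHKYFRHFSTGAMLDEDGATGYLIAMQYDI
>DQB1*03:01
FNTCMMYWFLTSVCAMNDPQSSVWHRKTDKSCMYNYNTQMADRLCCDKLVTGPMRFWDSK
YAQQYSWYFRHFSTGVMLDKDGAHGYLYAMKYDI
>DQB1*04:01
FNAHMMYWFLKWVCAMNDRCSSVWARKTDKSYMYNYNTQMADRLCQDKEVTGPMRFWDSL
YAQQYHKYFRYFSCGDALDEDGVTGYLYFMKYDI
>DQB1*05:01
FNACVMMWFLGWNCRMADLQSSVWHRKTDKSYMNNYNTQFADVLCQDKLVTGPMRFWDSL
YAQQYHKYFRHFCTGDMLDLDGATGYLYAMKYDI
>DQB1*06:01
YYACMMYWFLTWGCAMCDLQSSVWHFKTDKSYMQNYNTQMADKLCQDKLVTGPMIFWDSL
YWQQYHVYFRHFSTGDTLDEDGATGYLYAMKYDI
>DQB1*07:01
FNACNMYWGLTWVCAMNDLQSSVWPRKTDKSYMYNCNTQMADRLCEDKLVTGFMRFWDSL
YPQQYQKYFYHFSTGDMLDEDGAGGILYAMKYDI
>DQB1*08:01
FNACMMYQFLTWVCAWNDLQSYVWKRKTDKSYMFNYNTQMADRLCQDKLVTGPMRFWASL
YAQQYHKYFCHYSTGDRQAEDGATGYLYAMKYDI
>DRB1*01:01
NYHFCKAAVWICCSFNYGFKPTATIYHPGFGRLVFNYSSDKMMFWVQTMYTKTFCLDSYK
GSFPPCSNVIEIVVCYSWYSFSMIGSDQYNQPQF
>DRB1*02:01
NYHFCKAAVWICCSPNYGFKPTQTIYTPPFLRLVFNVSSDIMMFWVQTMYTGTFCLDSYK
GSFPPCSNVIEIVVCYSWGSFVMIGSDQYNQDQF
>DRB1*03:01
NPHFCKAAVWICCQFNYGFKPTATIYLPGMGRLVFNYSSDKMMFWVQTMYTHTFCLDKYK
LSFPPCSFVIEIVVCYSWYSQSMYGSDQYMQPQF
>DRB1*04:01
NYHQCKAAVWICCSFNYGFHPTYTIYMPGPGRLVFNYSSDKMMFFVQTMYFKNFCLCSYK
GSFPPCSNVIEIVVCYSWYSFSMIGYDQYNQPQW
>DRB1*05:01
FYHFCKAAVWICCSFNYLFKPTATIYFPGLSRLVFNMSSDKMMFWVQTMYTKTFCLDSYW
GSFPNCSNMIEIVVCYSWYSFSMIGSDQYNVPYF
>DRB1*06:01
NYHFCKAAVWHCCSFWYGYKPTATIYHPGFGFLVFNYSSDKMMFWVKTMKTKTFCLDGYK
GSFPPCRNVIDIVVCYSWYSFSMIGSFQYQQPQF
>DRB1*07:01
KYHFCKAAVLICCSFNYTFKPAGTIYHPGFGRLDFNYSSDKMMFWVQTMYTKTFDLDSEK
GSFPPCSNVIEIVVCYSWYSFIMIGSDQCNSPQF
>DRB1*08:01
KYHFCKAAVWICCSFNYGFKPTADIAHPWFGRLVFNYSHDKTMFWVQTLYFKTFCIDSYK
GSFPPCSNVIGIVVCYSWYSFSMIVSDQYNQPQF
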
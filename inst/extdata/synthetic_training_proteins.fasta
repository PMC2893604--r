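>synth0001
KVSDWCPDENKGSAMTGAYYELEHDTGIGCYRIFRANYLEHDAIEGLVCMTMTPCAYLEH
DGHDESDCEPFIQRKLVSLHYHDGTKYYTGDHDEFDGVQQTTITERT
>synth0002
TELEYNEEPILEHDPMESAEAHVALFDSSWPFVCHVASRPYKQNTRCPNVINWEHDSPIE
TDLCWELLC
>synth0003
CYYVDEHIYEFGDECDPGWEHDTYWRYVKWNLLPWERAVDEEDSCYCMHTLDMFEFKTKN
YILLNRVEKECKDTRRTMWDWEHDPLAYECTRGFTDVC
>synth0004
MSEPQCRFCLSFVKQRLLTMQGAIMLYVKNTYEIGVVWLIFFVDAIGGFEDNVDDPIYLM
VDWKKHKQNCANQWVSIPWYLQRTLTACRQNKYLSKWGDTNIFCRQGIPDPMEFCRPRVN
LMNAALDRKCCWVDSYYNSGCDTAES
>synth0005
ASVMEALQGDEEDERHTQRCAWPECIIIIHVPNHDHLIQAGSVETDKPRHIGALNKCKPN
WWDSFGKAEEWNWRACMSHKNGKHYGFGTQTHNKQDVRKRWKFVVDDWRKPRLEHDLLWD
QKNKATIYPD
>synth0006
NPLEHDADEPCTRKICMVTPQDHDEVDHPMHTLHTCDELDLWTYMGMNLAMRAVAGFYFM
FWLYGNPCPEPLNCDVMDVWAKVGIIHMQKVQAFMMAPDGHCIGVETDGYSWLDCLIQSR
IVRVCSHLMLHYSGVRAWERGCQNIYYNKTHHSVLVS
>synth0007
VMEMMMWLMAQFNQFVPEKITKKQTCFNTDKIKAFGLPPQCTLMDQQATMVFIIGAKNYH
MPSNMDAAHGLEREIWLKSQCDYLQKMCIPHWYEFSAHAAFRMGIIQIRQDIMENISVYF
FRRTDLECDEDEYDSRNFWPRK
>synth0008
AFWNYFLTDHWWPNWTAIDWQMEMWHYLMWIMWIWTTIHNKLEHYHASEYMNFGSYNRKW
NVLWEHDWARTPKFTPHPVGPWIFCDHWMQCRGCMSMYSKHHQDC
>synth0009
KGRERECCIISETPENWVSDSPDRFYTVHGLGFITKMKGGEKETFSISFKLENGWIVKNK
LKACVKDEFDQTSGWSCTEMAEMFLLIETDWLRFQSENLLKVVDACKSMTTQFRHQGMDL
FHTMHIYVCCCSPQ
>synth0010
SAHFLKAGNIDPCPRLCHYNGGSKRTLNPDYEPCECPSLWDSEAIATLRFRWCELKHEGG
CFMTEDWYAVELTIQELETDAGIPEDQNLYGEQRAAQ
>synth0011
YEPIICNRMDMNIYAEMMNFHELIEFRYTIMGPWIKYIGTFDLTYHIKMYCYMCQEWFRE
CHMVMHHQYYTTQNYASCEAD
>synth0012
ATTAHNEGLCATGSCWKVSDQEWWSQSGMRRCYTAFMPQWKNRPFCSFCHMNGTEVPIKN
WRMFCR
>synth0013
AMDEWDIRHDLRHIEHWRQLEHDGKVPGMCGQWRPECDLVHIHRKDVYDEYETSHNEAWE
HDASDGHGIREGGYE
>synth0014
VKTRMCKYPWHELLEKVLRRFQCRVCVDDPGICQSLDKVCDYCNAEPTVWDHPMKMTISD
ESDTFYKNEFLGHWQNSSGFWLWFAFMLMEQEKANVWVNQFVSHLVWCDEYDADGNCHTI
FQWWSREEMFKVSVALFHCPCEQV
>synth0015
QNGIYWKKQQFADDWLLEHDDYIDFWHKPRHHNISLAKRYKYTEGHNEALCAAPQGNCHK
NFEAHPNCGYGMSNATETYLLLCINGHQCVAPCDTNGASKYSAPDTVHHMFWRWHWGKTW
CQNMYANKSQMHVDRVTDDCPPQLCIWFPVFCREWCVQL
>synth0016
HTGYTFLVHWRNLAFMKQKAHIKDYIGKMCSWHFFGTEVKHVSIHHHAKFRSANYQMMEK
HNYRYRNAASVEQLIASSSTGPYSVCYRIFMWPDSCSCRCEMDKLHIPTKLDTKQDHYMW
AMMNFLLPFFYFLGMSNGCIVVFWPMEESDETDPGRQGH
>synth0017
NEDCVSTPYNGMRSVDMLCCLRDEVDDLVSPENAVFMQGKDIWGSRCKNQYDDLTLESYQ
DCYYYKGIQWVRFDELDSDGMYWFTHPNYSYCSLMYVEHDANDDILHRA
>synth0018
ESSTWKAPEGAATWIQITRSDSITRGACDDDELSEIFHCPEKMARLRCKQGKQDVMVEYC
WSGKYEGWVPYGYIVATDQALQMSHPLFQMFEYVCALTCYIETDASICLQGAGQMCLRQG
MWSYLGRGQSGPCSMGGLHRVQQWCMDIHREIQ
>synth0019
TGHIGYEPWFEVAPNNTESTTVVCHVVGLISICFVITNYRKPPLWMEADLAEYMTIYIFI
PGYVSTQMRTTAAMLFCDCNDEFDNMFQGSWDPFQRNIPHDVYWEEDPKLQWFRYTAMQM
RRHKCMYAWDLITCVIDKANLQQPMPDQDYLNRAYASVG
>synth0020
RARHQEPDVYQMKAECHIKYFLQYPFDGHWKKLNTYSQFENPMRFFMFEWHGPQGPPFRR
PLWVVSLEHDEMGVFEEMCTAWRVPDSDALSSNSLLQIKWRWNLFDQISRNCKSCRMHPV
NHHSSVHVTNQFHVPWHQLHPHEAHMAHYAKEHQE
>synth0021
ALVGKLKPAMNDETDGMLWHNPDRIYVDQPDVMMIMYLVIYGYFHDNRTQGHNRWHFWKP
FHRWEDELDSACQPMRPV
>synth0022
HHRFHCIQFRYMMWEHDKMWLELIYFEPPKPIEHDAIGCQQMHGISQWLNWIKGNAWDSE
PLPWPWTHGQKKLTYDMVPRIHAYNNTLCKNNHCCPQEILIT
>synth0023
EDYEAHPVIVGIHGPANGGNEIMCCQPIVRWVRSNSYNRETKDCKPHSKKGVLHVHLHKH
YWKAKAPVPEWWEGCWHMQHWEHDA
>synth0024
HTGCHDEIDGVVFVHMCSDESDFMVEGARYIHVFQITHCRTENWVGDEHDRTWIYVFYKM
NSSHTIKWEHDAKNVWNVPFVCRTPNCNPSRDLRECPGGIIYMWTSFS
>synth0025
SNIRHSTYCCESTENWGMMLPKDMPIHVGRKLATFRVMISSELVRDVSGGNCEFMTEFFN
NLFYLEYDFWGRIKHPNLPNCPAMWWL
>synth0026
FHEVKYSEEKVNTKYQLIWALLRFIMMLTITIPIMGKFYDTAVTFQFYDEMDSWMCQHCV
QCDWHMSDLNQAVNGITYNNHKFWVCDNMTGC
>synth0027
IAQFDDGMTFQPDLVPFRAKKNQTYLIEHWRGKEDEWDAPVTGILGQDVPSCNTDEQDGK
QYLYDHMKSGNLTVLSTKDSLEYN
>synth0028
GRGQYAVWCFWTLFGTNNYHLPRRLRWNCGHVGNIPAEFTNGCLHHKTLYDQHGMLEHDA
QCFMFRAAITTDWWLTQDTEDTEHDTRDEQIYIFARYEHPFWDDETDFYIAMWTWSCVVA
WNEHHGTMKLWHTHEGDFIDRGLQFVQK
>synth0029
FPSLCMVIAQLEHDSETVNHWFRHEQWFFMDHMCMEYSWSVMSCLGDIKNLYVPQGRRDE
CDHNESPDTKFEVTNQPLETDGQATFRPVGHQLGLPGVHIVDDYYTGKMSSGAWASPGVA
FPFACDEIDNYF
>synth0030
FTWELIYELFFTAWEWDAMYRIDGRHNDEWDHRHTAHVIFSMGWEHDAGEQCRGGNICQQ
DRLFTQNKMSRCHFSYWIIKDGHAHRRSKYMPYKREKGMKMQEGRNGRTATWRDFYNLTV
SENVTDHTCMDNFYMDMC
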
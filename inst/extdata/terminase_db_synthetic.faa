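>TERL_SYN01 synthetic marker terminase large subunit
MSLAHLGYQNNRCPSLEDLLIRYGCRCLGRLTRQVCPRKYVLIKYWVRGRVFLRDVYLTTGSLLTNYVMV
EVRVRGAVTGRYRGVKTNYTKLYSDGWTATNECRLPVLINYTVNGAELISHLCFLVFGVMTNYDSYRTTI
QRCGRRIVTKRLINYAIWDAPNIVIIARGPRGRLTNYGFS
>TERS_SYN01 synthetic marker terminase small subunit
MYRLTSPASAAGERYYEWTLTNYNETTVSISVMDDLIAFAALTNGDCMNICFRCSACLHSLGLLINYSSG
SCASRPRPCLGSLQLLTNYR
>DECOY_01 synthetic decoy protein 1
MGRYYNGINGHWLGQCPVQGAWWIGNGIHMTEPISQYHPNSAPGTKHWVSMLHWCLAMRLSNHIAWDMAQ
GYKFQTDDHQDWNTKVTVRHRYWSWECSANHKPCCWTCMDDQWPMSIKVLRYFFHFNQGYSRCADKGTYF
K
>DECOY_02 synthetic decoy protein 2
MIETKAYLQLGVSCIQEIFIHYETLEKKRGGEDDPKHQFHYYLIAQNSNLCTAEFNRQRTRVAILHHMVK
YCFMCYDRGKRFQFMMTAPAWESTHGYSCPDLGHTAADMPVFSICEGTKPQKMIDWWAYEPAIFLNDDEK
DDYKWNVNHEWTFWYKRWFQHPRVGCATPPICKIYQYFLNYRCAFFIPELGVFYAGQPITWSRSTWQ
>DECOY_03 synthetic decoy protein 3
MIYWFCFNDVQPRCPSHSTMKIPGWSNLAGTPCRENFGWYNDERQPDQRCGWSYEQSFDETRDSSEEYFA
RFMNYMGSEGYIAIMMTKVWNIGMWFCHLIDMPWCIGRKACKTFLCFQGSFTAIWTYYSTFAACEYGYCR
YVDYCRLPSMESRPWSHVAEFQECAWTWPVHEHKIYATNDVDRHAYKQYSNNQSANNVIFNKCKKKMLGC
DACWFCKNKVCRPHEGVSPSISQGIDIF
>DECOY_04 synthetic decoy protein 4
MPWDFPWQEYPDILPLGLHVWVQRRLFATPGNKAALPWINMSMGIHDLAFFEMKCLCCNGQKHWFTKNPN
DICKSHFHHNNCYYWKYIDSHLWDPSWQWLCSMWDHNIPYVLC
>DECOY_05 synthetic decoy protein 5
MNLNGIPMPCINWYDENPHDFYYRGLPNTVYHQLSAKDMIETFLENFTGQWAAKGNLEVEKKMHEWEDSD
KEYQQQANANDWMVVCHYQSLAYHEFILPKAPMYYCKRPFDYQTAQSIWVCQESEQMPSEFNCKLQYGFW
WVCTHYHILM
>DECOY_06 synthetic decoy protein 6
MPYGHFTIGGLMLQMSQKAEHSIYEKSTLAITPPVLKNSEGVDTASQAKWLHQLTQYRATHFIMGRIRLD
KQWISPKRWDMVRDWQERPMIFATSASECASSEWDKFMRFMLNLHFQTKKYRNRRPEHASWSNTCTLVES
HGHFRAFELNQYRMCEKLLPFWCMMFQFWHRQMTLIDYPGPLHPANYHLALFWTAICHHSCGGTCAFADG
EPYYDHSIDTAV
>DECOY_07 synthetic decoy protein 7
MMCMMQANDCHYTRHHGCFPFIGVWRVLYSGMNYKKGDNVDTYIYPIMREIYVIPNKKRQHQTMDRNCWS
YPYPGVDSMVCESASLELRPHQLRTYAHGEPFIGTYLRIMDPCQHFERCHIAIKMRITVMSRFCWHKRRK
RRRDVEIYTSGRWPGRLWMMDRENVKWCKQVLGCQESRIDMVLMVEYSPYASCEQGSVCFVFYLCRKLQY
ICWPMKCKMI
>DECOY_08 synthetic decoy protein 8
MGELKNHCPMHFKLDMCKSTPLLQDQIPEDNDDPYKDTQIMKDSWSGIWFQPKPINYKSKLRFTYKSHPS
DCCNHWQCQELFEVENWWIPCFPNVNNKQNQYMNSKQMQRHICSQVCWLNMFANNDRWNNMKHRFDGGLD
PMYVRQTNKSDRKHKVHNEKVVYDDDFCEGSMINCYYDCHMFHVPMMFWITMRVQFFFVILWPMGVPRWL
VVQHFEQVS
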
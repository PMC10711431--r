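>seed01
FRIQSIRADLKLSTKMCKKTYAWMLIGGKAVNEPCMLQYTEERCEHADHDDVEKCCAISIAVATQGSQPGLAGKTRLDIL
PTVAKDGLLADLRAEREIRQDEGEDSRRILTQDYNLLSTQVYTQRTLHGRYTKMQHQAIDAIKSKQGMSLRVEAPDGIKN
DVPGFGKVAGRVEKEAQTNAYSAKRLHGASGNNILLILRIFIQKGKHLLSYDVLKQTVIE
>seed02
PRYQDIRADPKRMSEMKAKEYTWMLIHYKVRNEPLQLGYTEELCEKVRGDVVPVLRPGAIQCRTQGQITGLAKISKLVWR
TYVPNTILKKDLGKGRVNRDKGTEMKYDIVTQRKIQLVNQAETTVEYHGRPIDEQTPGRDTKKNRHCQSVRGPEQAILAP
PATGSAKFGWRENVVAQSIRYGVSRKSIASGNAALLIARKFGQKLKHKISIDVAKQYGIS
>seed03
YMPQDIKIDVYFMSLMAEGVYAWMLIEYKQSEEPGQDGQTEELCLVFDHDVVEPLGPGANNERTQGSNLGLAGKSRTVIL
TAVSCTGLLYDLGMERDYIDYLLEEHRRIKTQRKEILGTNVGTTRIYHALSTPMQGQTRDTMRLRQGMSAPVNEPDGLAP
MILPLGKVNGSEDKEGLMNRQFVSLPYTASGNMALLIALLFVQKAKHLSAGDVLKQEVNH
>seed04
NMYLDIRLDLIRMSKMIEKLLAWKLIEFQPRNELRSGGGDINLCIHFSKDVVENLMNASVPCYTVTEQAGMYGKGLLVIE
TAVDNLGQLSVNGEMIPLHDDGGGMRLRILTLPKIILVTQVETTPEYHGRYVNMPTLARDAYKNRDYMSTRYNLPMGDIP
TITKIEKVAGRAEKAAFTLRYSLSRRYNARNNAALLIAREFPQKAKHKSIRDVLKVDVSF
>seed05
YFIQDFRSIIKKASKKDAAGYRWMLIYYKQRNLPLQTGLYEELCEHFDHDVVINLTVASILCRTQGLQSGLAGFGRPNIV
AIPANTPLLSFSGEYRVKRFDLGEMWTSILTQRKIIRVTVVETLRSYSERYTDMQTQVRDALKNRQGRSAPINEPNGMAP
ELFGIRIRAGVEEKEQRPNLYFVSRRENTSGTRAKLIPRAFIQMGSHNFSIDVEKDTTEA
>seed06
HMSQDTRADPCRAMKMCAETYHWMLKTYKQRNSPFRPSYTEPLCESPDDDRVLTLRIGSIPEVTQGSQRGLEGPGRQVIL
KVVANTATLSRLGSYREDRDAQAWMERRDGTQSKIGLVPQRETTREYRGRFTDMQTADRSELKNRQWMSATLKENVGLAA
AITGLGAHAGSEEGTVHTNYVFVSRLANKSGNRALQNITRFGQKATHDSSYDVATQTVIF
>seed07
GMRQDIGLDPPLMSATCAKTGAWRFLAQKQRNAPLILIYTLELCEGEDHSTVENLKPWTSPCLTQSSQKGLAGKTRLTIL
TAVDNTTAISQNGPYRVIRDDQGEMHLEYLEVRKIILVRMWETTRGMHCIYDVMQTQARLALYYRSICSKQVYEFNGLAP
LITHIGKPAGREEKGAQTNVYFYSRRYHAELNAGLLIAGRFTQTAKHKSETIVATVTVSL
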
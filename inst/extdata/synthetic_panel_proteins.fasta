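>P01210 synthetic parent protein (constructed context)
MAARDQISYKIPSCFSKKPRDTCGFCNMNGCYGSVAFRMCEWNKIAQTYACHRIFEPYWG
PVWEEFLANEIWLGLIWHADGTSTLRENSKPEESHLLQHMWMDVQNILFPLERAKDN
>P02654 synthetic parent protein (constructed context)
MMAADKVIICVSAVETHCALKFPNYPSNLGACIQNTATMRFFWALVHWDPMDYASQSELP
RDAGRPAASETFQKVKEKLKIDSPDWGWMPVCLAVRKQWAPQT
>P05060 synthetic parent protein (constructed context)
MHNICKDMDVVILWTRCNQDEDYIWGDKPATMFREQWCFGCIAINFGPVRARWKQCKTDR
DPTLQINQWEAPSKQLWICRPVDDLIRQCGGLQFGDQYDVWCRHAAFKRKRTAWPYKHQI
DEAHRHDQNYIWLGWWSAIEVTVGNKTGFGPFWPCTPLHNVFWNFMSHWNYRGFPMITSS
NLNQGRSLSQCIWANRSQTHHVYGKYWDTHYPQRHQVHDPNDYFQSPIASYNGCFLNFKG
FPDHGDPWMSITAKACESPLSHHKYRRLISGDHHAHAGVSIGNPIYYEEKGTCLLTTIVQ
IQMFAHEQGQDETKARQAAWSATHAEKRMHQNVFEKIMVIECMCIWFWFTPCNCLPMHWF
IECSCRLYRAYVPQSPQHWFSHTHGMVIKPPNEPKEDHWAHFVHYMEGYYPLCTNSEIWW
MHVREPRAYFMSDTREEDISTGACYQDRWPALEWYRR
>P05976 synthetic parent protein (constructed context)
MAPKKDVKKPVAAAAAAPAPAPAPAPAPAPAKPKEEQLSFCMNTLNQRPDAEMYGP
>P07196 synthetic parent protein (constructed context)
MHPCWCHMVLCLRRETRTCDQPQKSKYCIVTYVFKRNAMNYYHNEEMSFQFTYFQPNEDC
NASHHPDWYLFKMYSTELPHKEGITENARSWLGNWYYRSGQGLHWISVYANWPKVSYLIQ
GDGMQKLPLQKHFLQVTRYHICFLMYASERYHSTSFHRNAKIIKQWFDYECMKIGICESE
PWDHCANTRGSDCTLFYSQCEWEHCLCDTKQHWFRWERKEMWEKLMEGENFVGPVIQLYG
VPTGKSIYSPNFDTLDLMNTWKYSCMQCRKIMTFTYNMKQNDKEDWREIWDEPGKIIKND
TGLAIWCLYNTCQNDIWNVFQEQYRVKYRDKFPHRPRLDHRRIASEHFLQGMTKHPTWVG
WYMYGLPWMGDTIFTAWFCFNFRRLCAWVWQKIVTALLNSCPACHQVYTYAAFCPTTVWN
IGIGVYWWFHNTPESVDSFPSYYTSHVQEEQIEVEETIEAAKAEEARSWNIMCEMIRPKH
ENEWFC
>P46821 synthetic parent protein (constructed context)
MIYVTWRTPVFIFKNTRGHHKSIFLWMGDMAHLRYKSYWQIYAHCNIYWEYDIVAADGAV
YQKGHRQAYIPMNVHTITTFGYDQNWFSSWVEIIQHTIADPINYLNLVARVRQEWDIFNT
MQILPFTDELYHACYWTQTTMECFGEDFPYGHYENSMPSWPVRIKKNDLHVCRDDAESSV
THNILAVRKMVHAKACVKHLISSYLMHHWMVHWKYRWQGRHTVISYARPARTSSLLWRCE
CRFNMGKLGRVKNANQWQNINPTEWEADPKMGMLYNISSWETYGGLGVTRRNWPAGPDQN
VRMELMSSCLDSCGLNGFTNWFRRQETRPHTKIMTGMQGEDLNGTSKIKMMDWFTLYYTD
FIACFGTHPMEMEAGKEAWPQQLWMADQRMWHYNTAHPRCVEPMNTHCENCHKCPQKDSQ
TLPHDPFSTRKWLFCFAMMIWAGNRESTSMPYIEKPCGNKEGTINGFIKQIQPREQLCDS
GVQFSYVQRDITDKAYMTSQDFCERNMYTQIKYDEPQHKMVLMTSCNMIPQNTCSDLKMV
CLDHPINCRMPWSMYTGPPWTKVMCGLTCRMEEPYIREGWVDFEHLNNTKAKGMSTCGSK
SSRISSTASWYEYLEQSVRWTWCFYMLFPFLHTSSDYYLGTCAKDHKLRNPKHRFFRVWY
AVITDLWPTTWYVVFSMHMCFWPVRWFHAQNFMNLVLCFNMYGDFTFCQLHFITCVYTKY
HDIMFKEPKKEIKKLPKDAKKSSTPLSEAKKPAALKPKVPKKEESVKKDSVALFLVMQIF
PADARDHNCEDN
>Q8N126 synthetic parent protein (constructed context)
MPEKIGEMLYWRWPRKPKDMRVHDFEENNNREEEFAKYSQYQFSGQWKHTWARECVKSGF
REWGFLCNTDDTWLKIEDEMHSTPAPACYRVTFPYQLSHISDPRNTNGDYVNEPKRGYRQ
FPKNADCICVDFFCLWDLGKDQQGKPMQDNVQESGRCLRVHAMMHKMSSYPMKDPQPYNA
MWAGMQDQFIWVMFFQIAQSRCINKLMCYSYVLLWQEGYWVSITDPMTMDMFDPIMGRGI
SQTGGFYGTEEIFIDKWEFVDGHKRPQWNKDYGWMHTNIMWGYKCRRHNIRDWFIFKVAP
KLCNKDNWMKYSTLNVNDPSPVPSSSSTYGLWRWDFNMVFFQEDSQWLN
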
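>hk-actin-like synthetic housekeeping-like template
MFIILAFHTERVLYWQVFPAIRTLTHYPNQVPAGLGYARELMAMTNSPRFMMWNFWQEGMRQMPKKKIPARMVRDSMMARYAANKHQKAVQAIAYQYGGFMSPQNEFLDKVSYNLDTILMADEP
>hk-tubulin-like synthetic housekeeping-like template
MNYYRNQRIWILYNGVAVVSLMKPPVRKAQIQQIFAGNFDENVLPTGAPIRVHSWIREYFPWTTEPAGGLNPNFPEPQTPSFDRSDSHIAVSHFRFNADQESDNMLWIDITDKDTFVTAVTKAASLINPKFSRAALHRPTWEEFAFNGDVFYFDNLAIRMGWPRYAYILAERGMANMYVEGQIKTRTN
>hk-ef1a-like synthetic housekeeping-like template
MGRLVFAGDHTNLVNLDAHLESPLNRNSGFLKLEVRSPDKKNGILSIYSPFGGPDFRQGIFVTENLVAIENQNLGLVLIGGLRWTWQLDPPNQIAQNELSLNQWSEPITLVLHKTELIKARYAILVNFDTYYNQKALEALNGDKIRPWYEQ
>hk-rps-like synthetic housekeeping-like template
MEEATRQWDVAEIFAKVDEDMKEFSHFIHKYFNTPDSHAGFFIGIPLANPETVTKKADLIDRQLPIYEDEDIIAKEPWPLIWSGNPWDIRDSQAFNAMPTQTAKGDGALEPITNEFTMKPFSERFGIK
>hk-rpl-like synthetic housekeeping-like template
MDIREKPSATDGGELERYPLEDFIELHGMEQVTLNLPGTSDDHNLNNSIFKFQLQDFRPFFADEGVKFTYNFKRPAGIWLGLNDDEETMIKKVGDVLMRVAPLRLPAHFLSMRQIFDANGKPIRKLNYLVFYPPVPIAVTEKYNVRFFGNRTSNR
>hk-hsp-like synthetic housekeeping-like template
MDALPLFEQFIGAPDFLQTAYEMTDKVRSSEPWFDEESFGGQVQLIPEKGIKRAKRSTMMVQSRAPNLTVIQKVDPKRSKGALAEINRFQAPEALTPWRVIYHTTDSHLIGREETRIIPVYVILDKVGSNQISNWAVAPLEGPPSAYVVEDGIVKDGKNNANKMEIQLNAYFYHDPGKRPRIAKMHMTVR
>hk-atps-like synthetic housekeeping-like template
MRAHQAYQPSPKDQLGGLIEQNILTNAVGLSTDFHLFFLFTDLMKLTNIQMAWLVGNHATFWVITYGNKQFFMLPIDKVMFKLFNDEPTTVKKEPYKLKWFIDSTDLMNWDTVSNQFIHKRTQFFWPNLAVKLY
>hk-gapdh-like synthetic housekeeping-like template
MPIPATLAQDLMGQGANESATIYADAPLERWTRVGHNKMVPGYHEAFRVIESTAEIEAQNGYYSDFGGVFWQPITHLAVTSQAWYRTAPDFWIERATFMRLLIWGRDSYLSNHYWSRMRFLYSWFVRLLIETDMADWIQALSFPAMQKVPAIWKTWQNNSGFTASKP
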
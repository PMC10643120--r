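>gp65-66 NC_028999.1:53811-55004,55455-56447
MYEEHNLRRAVREIHAKLLGHAALDPYYGTTSAARGAMFLSHIGQAPVVEGNEPRRVMTG
MEMRYAEYTFDVRLPTDCTILHKVRKYPTGQGYGAIQHNPVTTLIYENYYDEYKTIGVLH
VPEYMSFHQDFGYELVKNKEVWESLQPDQMFAKDTVIAQSSTVKSNGLYGMGVNANVAFM
SVPGTIEDGFVVSDEFLERMSPRTYTTAVCGAGKKAFFLNMYGDDKIYKPFPDIGEKIRE
DGVIFAVRDLDDDLAPAEMTPRALRTLDRTFDRAVIGDPGATVKDIKVYWDERQNPSFTP
SGMDGQLRKYYDALCTYYREIIKIYRGLLARRKDKLRISEEFNQLLVEAMIYLPQAEGQR
KLTRMYRLEQLDEWRVELTYESIKVPGGAYKLTDFHGGKGVVCEVRPKADMPVDEFGNVV
DAIIFGGSTMRRSNYGRIYEHGFGAASRDLAQRLRVEAGLPRHGVVPEQDLNRVCSNREW
VTYAFAELQEFYYIIAPTMHEILREHPSPAEYVKTVLRDGFSYIYSPVDDPVDLMSSLNC
IMNSRFCPNHTRVTYRGQDGKMVTTKDKVLVGPLYMMLLEKIGEDWSAVASVKVQQFGLP
SKLNNSDRSSTPGRESAIRSFGESETRSYNCTVGPEATVELLDQTNNPRAHLAVINSILT
ADKPSNIERAVDRTKVPFGSSRPVDLLEHLLECRGLKFEYATTDGVQPVHTAVPIRAQQK
VKSEAIEE*
>gp67 NC_028999.1:56450-58420
MNQYNARDLLNMSYDDLFAIPNEWHKIIFDDGEILTKDRATKLSILLWHPLKQFPNATLS
VKYHLGDTRVTSKSLVKLLNSVIWGIHAWSNEQVDPEVLARLAIEAKNVLYNEATSRLGA
YVATLSMFEIAEVYNHPKVREANQNIEPTTHGIETIAYGKIKEAFNDPTQFRGNSIIEGL
RSGTQKMEQLLQAFGPRGFPTDINSDIFAEPCLTGYIDGIWGLYENMIESRSGTKALLYN
KELLRVTEYFNRKSQLIAQYVQRLHKGDCGAGYIEFPVIKAYLKSLRGKFYLNEETGKRE
ILQGNETHLIGKKIKMRSVLGCVHPDPQGICATCYGTLADNIPRGTNIGQVSAVSMGDKI
TSSVLSTKHTDATSAVEQYKITGVEAKYLREGQAPETLYLKKELANKGYRLMIGRNEAQN
LADVLMIDNLSAYPPTSASELTRIGLVRTVDGIDEGDVLTVSLYNRKASLSIELLQHVKR
VRWELDNRDNIVIDLNGFDFSLPFLTLPYKHVNMYEVMKRIQSFLHSGSDTEGSKLSSDK
VGFTSKTYLKNYNDPIDAVAAFASLVNEKIQLPMPHCEVLVYAMMVRSTQQRDYRLPKPG
ISGQFEKYNKLMQSRSLAGAMAFEKQHEPLNNPGSFLYTLRNDHPYDLAVKGGKLY*
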
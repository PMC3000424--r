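>syn_chl_001
KWCMMTPSGWYKTMDMHCYFPTAHDQGCLWTCDFLRQVGDYTKQQCTVCPDGTCIYLWIKITIKQQTTYGCPPTMDHCFW
HLFCQFYKLRMKIRMKTCWQCVKLYMCMDCKTQKLVEPKYDRSRKVYCARERDDHVLGEESGSHEEFTMGEWCVWHDIGV
TRMDYRLQMDMCWFWSQMWIQVKTGIYLVRCGWMGTIGTGWPEGVYKCCNCVEMWITETCGHEIPPGMDTNMYQI
>syn_chl_002
FELNMEWSQWFMCMMYHYGAQTRDEHVCKWTEIHMDFDTCKFINGAQTCCTGCTHSLDVVWRSQQEQYDTSCCCMVCQSC
WLTGGRLWLVCCQRYQMRTYVIKIMWDYHQKPHPWMRDAAIDKAAPCEIHWAGSVFIWQRATKAFGAELYVTLRRRLMDG
HDWKCFKNMYCWDLYNHTMWQVMMMFTEKMPTVAKGQCITHLWCTFGPTMDKTWCMWNHR
>syn_mit_001
GKWVMHYSDPCTEMTTMSVKQEWSLNLENKNMFVVLVKAFVDLTCGKLIDSKPIESSIMCEVMNSLQVSRECNVCMVYVN
DVGVQDWCPFVLYWSEEASRECHWHVFCVWLMLVVFMHSEPFFYNCV
>syn_mit_002
SSHFITSMNSKEKIYVVFQIVVSKVVYKTVFMPRVKIKGILVDKVGSTSINYERINSMESYWCVPMYKYWLHSSDCNYVQ
MFMVQTVNPTFMAIFFEWVCTFPGTQVVRFEPCAVKHITETKMNMMVLNVFVLGTPWNNWMYPGYVMVFAFVAVYMGPIV
TSWCAFAMGEDFKCIVTFFDQLQIAEFMQPFQCWRKGSRLKMTFDPDNYQINFQD
>syn_nuc_001
EHSTLYIGSSIGSWPMEWSCVKEWQSASISMFCAMTQEIEALFVWQSITMLIPLAYWYKDRWWWPMMIWCYYLQQLSVWV
RWTTNWWAHIMEYMIIAIVYPCPQNWEYKTWQWGAYLCWQVCTIWDPKRKFTQYN
>syn_nuc_002
VTWNDWTWQWLVRPCIWCYREEEESFWLEALRRGVATTSIIGLIEMAETLQYNPIEETWKWSENSSETHWCTWQSKYCTS
EYPYGSCAMITISWILESQSPSWLLGPIPIMNEVWRPTLESQSCISCNILYMHASR
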
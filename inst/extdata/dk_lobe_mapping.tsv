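parcel_name	node_label
left superiorfrontal	left frontal
left rostralmiddlefrontal	left frontal
left caudalmiddlefrontal	left frontal
left parsopercularis	left frontal
left parstriangularis	left frontal
left parsorbitalis	left frontal
left lateralorbitofrontal	left frontal
left medialorbitofrontal	left frontal
left precentral	left frontal
left paracentral	left frontal
left frontalpole	left frontal
right superiorfrontal	right frontal
right rostralmiddlefrontal	right frontal
right caudalmiddlefrontal	right frontal
right parsopercularis	right frontal
right parstriangularis	right frontal
right parsorbitalis	right frontal
right lateralorbitofrontal	right frontal
right medialorbitofrontal	right frontal
right precentral	right frontal
right paracentral	right frontal
right frontalpole	right frontal
left superiorparietal	left parietal
left inferiorparietal	left parietal
left supramarginal	left parietal
left postcentral	left parietal
left precuneus	left parietal
right superiorparietal	right parietal
right inferiorparietal	right parietal
right supramarginal	right parietal
right postcentral	right parietal
right precuneus	right parietal
left superiortemporal	left temporal
left middletemporal	left temporal
left inferiortemporal	left temporal
left bankssts	left temporal
left fusiform	left temporal
left transversetemporal	left temporal
left entorhinal	left temporal
left temporalpole	left temporal
left parahippocampal	left temporal
right superiortemporal	right temporal
right middletemporal	right temporal
right inferiortemporal	right temporal
right bankssts	right temporal
right fusiform	right temporal
right transversetemporal	right temporal
right entorhinal	right temporal
right temporalpole	right temporal
right parahippocampal	right temporal
left lateraloccipital	left occipital
left lingual	left occipital
left cuneus	left occipital
left pericalcarine	left occipital
right lateraloccipital	right occipital
right lingual	right occipital
right cuneus	right occipital
right pericalcarine	right occipital
left rostralanteriorcingulate	left cingulate
left caudalanteriorcingulate	left cingulate
left posteriorcingulate	left cingulate
left isthmuscingulate	left cingulate
right rostralanteriorcingulate	right cingulate
right caudalanteriorcingulate	right cingulate
right posteriorcingulate	right cingulate
right isthmuscingulate	right cingulate
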
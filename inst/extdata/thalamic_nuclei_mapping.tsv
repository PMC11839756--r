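parcel_name	node_label
left anteroventral	left anteroventral
right anteroventral	right anteroventral
left lateral dorsal	left lateral
left lateral posterior	left lateral
right lateral dorsal	right lateral
right lateral posterior	right lateral
left central medial	left medial
left paracentral	left medial
left lateral mediodorsal	left medial
left medial mediodorsal	left medial
left parafascicular	left medial
left centromedian	left medial
left central lateral	left medial
left reuniens	left medial
left paratenial	left medial
right central medial	right medial
right paracentral	right medial
right lateral mediodorsal	right medial
right medial mediodorsal	right medial
right parafascicular	right medial
right centromedian	right medial
right central lateral	right medial
right reuniens	right medial
right paratenial	right medial
left anterior pulvinar	left pulvinar
left inferior pulvinar	left pulvinar
left lateral pulvinar	left pulvinar
left medial pulvinar	left pulvinar
right anterior pulvinar	right pulvinar
right inferior pulvinar	right pulvinar
right lateral pulvinar	right pulvinar
right medial pulvinar	right pulvinar
left ventral anterior	left ventral
left ventromedial	left ventral
left ventral lateral anterior	left ventral
left ventral lateral posterior	left ventral
left ventral posterolateral	left ventral
right ventral anterior	right ventral
right ventromedial	right ventral
right ventral lateral anterior	right ventral
right ventral lateral posterior	right ventral
right ventral posterolateral	right ventral
left lateral geniculate	left geniculate
left medial geniculate	left geniculate
left lgn	left geniculate
left mgn	left geniculate
right lateral geniculate	right geniculate
right medial geniculate	right geniculate
right lgn	right geniculate
right mgn	right geniculate
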
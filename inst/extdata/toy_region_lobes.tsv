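region	lobe
roi001.L	frontal
roi001.R	frontal
roi002.L	temporal
roi002.R	temporal
roi003.L	parietal
roi003.R	parietal
roi004.L	occipital
roi004.R	occipital
roi005.L	limbic
roi005.R	limbic
roi006.L	frontal
roi006.R	frontal
roi007.L	temporal
roi007.R	temporal
roi008.L	parietal
roi008.R	parietal
roi009.L	occipital
roi009.R	occipital
roi010.L	limbic
roi010.R	limbic
roi011.L	frontal
roi011.R	frontal
roi012.L	temporal
roi012.R	temporal
roi013.L	parietal
roi013.R	parietal
roi014.L	occipital
roi014.R	occipital
roi015.L	limbic
roi015.R	limbic
roi016.L	frontal
roi016.R	frontal
roi017.L	temporal
roi017.R	temporal
roi018.L	parietal
roi018.R	parietal
roi019.L	occipital
roi019.R	occipital
roi020.L	limbic
roi020.R	limbic
roi021.L	frontal
roi021.R	frontal
roi022.L	temporal
roi022.R	temporal
roi023.L	parietal
roi023.R	parietal
roi024.L	occipital
roi024.R	occipital
roi025.L	limbic
roi025.R	limbic
roi026.L	frontal
roi026.R	frontal
roi027.L	temporal
roi027.R	temporal
roi028.L	parietal
roi028.R	parietal
roi029.L	occipital
roi029.R	occipital
roi030.L	limbic
roi030.R	limbic
roi031.L	frontal
roi031.R	frontal
roi032.L	temporal
roi032.R	temporal
roi033.L	parietal
roi033.R	parietal
roi034.L	occipital
roi034.R	occipital
roi035.L	limbic
roi035.R	limbic
roi036.L	frontal
roi036.R	frontal
roi037.L	temporal
roi037.R	temporal
roi038.L	parietal
roi038.R	parietal
roi039.L	occipital
roi039.R	occipital
roi040.L	limbic
roi040.R	limbic
roi041.L	frontal
roi041.R	frontal
roi042.L	temporal
roi042.R	temporal
roi043.L	parietal
roi043.R	parietal
roi044.L	occipital
roi044.R	occipital
roi045.L	limbic
roi045.R	limbic
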
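Occipital_Cortex:
- Calcarine
- Lingual
- Occipital_Inf
- Occipital_Mid
- Occipital_Sup
Thalamus_Striatum:
- Thalamus
- Putamen
- Pallidum
- Caudate
Mesial_Temporal_Insula:
- ParaHippocampal
- Amygdala
- Hippocampus
- Insula
Orbitofrontal_Cortex:
- Frontal_Inf_Orb
- Frontal_Med_Orb
- Frontal_Sup_Orb
Frontal_Cortex:
- Frontal_Mid
- Frontal_Sup
- Frontal_Sup_Medial
Cuneus_Fusiform_Precuneus:
- Cuneus
- Fusiform
- Precuneus
Sensorimotor:
- Postcentral
- Precentral
- Supp_Motor_Area
Parietal_Lobe:
- Parietal_Inf
- Parietal_Sup
Anterior_Cingulate:
- Cingulum_Ant
Posterior_Cingulate:
- Cingulum_Post
Temporal_Lobe:
- Temporal_Inf
- Temporal_Mid
- Temporal_Sup
Temporal_Pole:
- Temporal_Pole_Mid
- Temporal_Pole_Sup
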
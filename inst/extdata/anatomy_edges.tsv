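anatomical_structure	anatomical_entity	subclass_of
lesion	anatomical_entity	subclass_of
body	anatomical_structure	subclass_of
thorax	anatomical_structure	subclass_of
abdomen	anatomical_structure	subclass_of
mediastinum	anatomical_structure	subclass_of
axilla	anatomical_structure	subclass_of
neck	anatomical_structure	subclass_of
RID86	anatomical_structure	subclass_of
liver	anatomical_structure	subclass_of
RID205	anatomical_structure	subclass_of
gallbladder	anatomical_structure	subclass_of
RID33779	anatomical_structure	subclass_of
RID229	anatomical_structure	subclass_of
aorta	anatomical_structure	subclass_of
RID580	aorta	subclass_of
descending_aorta	aorta	subclass_of
rib	anatomical_structure	subclass_of
trachea	anatomical_structure	subclass_of
lung	anatomical_structure	subclass_of
portion_of_soft_tissue	anatomical_structure	subclass_of
RID13296	anatomical_structure	subclass_of
RID7710	RID13296	subclass_of
mediastinal_lymph_node	RID13296	subclass_of
axillary_lymph_node	RID13296	subclass_of
aortopulmonary_lymph_node	RID13296	subclass_of
cervical_lymph_node	RID13296	subclass_of
inguinal_lymph_node	RID13296	subclass_of
abdominal_lymph_node	RID13296	subclass_of
retroperitoneal_lymph_node	RID13296	subclass_of
cyst	lesion	subclass_of
mass	lesion	subclass_of
liver_lesion	lesion	subclass_of
lung_lesion	lesion	subclass_of
kidney_cyst	cyst	subclass_of
thorax	body	part_of
abdomen	body	part_of
neck	body	part_of
mediastinum	thorax	part_of
axilla	thorax	part_of
lung	thorax	part_of
trachea	mediastinum	part_of
rib	thorax	part_of
aorta	body	part_of
RID580	mediastinum	part_of
descending_aorta	thorax	part_of
RID86	abdomen	part_of
liver	abdomen	part_of
RID205	abdomen	part_of
gallbladder	abdomen	part_of
RID33779	gallbladder	part_of
RID229	abdomen	part_of
mediastinal_lymph_node	mediastinum	part_of
aortopulmonary_lymph_node	mediastinum	part_of
axillary_lymph_node	axilla	part_of
RID7710	neck	part_of
cervical_lymph_node	neck	part_of
abdominal_lymph_node	abdomen	part_of
retroperitoneal_lymph_node	abdomen	part_of
inguinal_lymph_node	body	part_of
liver_lesion	liver	part_of
lung_lesion	lung	part_of
kidney_cyst	RID205	part_of
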
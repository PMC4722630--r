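anatomical_entity	anatomical entity
anatomical_structure	anatomical structure
lesion	lesion
body	body
thorax	thorax
abdomen	abdomen
mediastinum	mediastinum
axilla	axilla
neck	neck
RID86	spleen
liver	liver
RID205	kidney
gallbladder	gallbladder
RID33779	wall of gallbladder
RID229	ureter
aorta	aorta
RID580	ascending aorta
descending_aorta	descending aorta
rib	rib
trachea	trachea
lung	lung
portion_of_soft_tissue	portion of soft tissue
RID13296	lymph node
RID7710	submental lymph node
mediastinal_lymph_node	mediastinal lymph node
axillary_lymph_node	axillary lymph node
aortopulmonary_lymph_node	aortopulmonary lymph node
cervical_lymph_node	cervical lymph node
inguinal_lymph_node	inguinal lymph node
abdominal_lymph_node	abdominal lymph node
retroperitoneal_lymph_node	retroperitoneal lymph node
cyst	cyst
mass	mass
liver_lesion	liver lesion
lung_lesion	lung lesion
kidney_cyst	kidney cyst
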
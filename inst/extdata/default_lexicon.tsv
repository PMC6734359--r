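canonical	entity_type	subtype	variants
infarct	ischaemic_stroke	-	infarct|infarction|ischaemic change|ischaemic damage|ischaemia|ischaemic stroke|ischaemic event
haemorrhage	haemorrhagic_stroke	-	haemorrhage|haematoma|bleed|bleeding|blood|intracranial haemorrhage|intracerebral haemorrhage|intracerebral bleed|haemorrhagic stroke
stroke	stroke_unspecified	-	stroke|cva|cerebrovascular accident
subarachnoid haemorrhage	subarachnoid_haemorrhage	-	subarachnoid haemorrhage|subarachnoid blood|subarachnoid bleed|sah
subdural haematoma	subdural_haematoma	-	subdural haematoma|subdural collection|subdural bleed|subdural haemorrhage|subdural hygroma
microbleed	microbleed	-	microbleed|microhaemorrhage
haemorrhagic transformation	haemorrhagic_transformation	-	haemorrhagic transformation|haemorrhagic conversion
atrophy	atrophy	-	atrophy|cerebral atrophy|involution|volume loss|atrophic change
small vessel disease	small_vessel_disease	-	small vessel disease|small-vessel disease|microangiopathy|microangiopathic change|white matter low attenuation|periventricular low attenuation|leukoaraiosis|small vessel ischaemic change
glioma	tumour	glioma	glioma|glioblastoma|astrocytoma|gbm
meningioma	tumour	meningioma	meningioma
metastasis	tumour	metastasis	metastasis|metastatic deposit|secondary deposit
tumour	tumour	other	tumour|tumor|mass|mass lesion|space-occupying lesion|neoplasm|lesion
recent	time_recent	-	recent|acute|new|fresh
old	time_old	-	old|chronic|mature|established|longstanding|long-standing|long standing|previous|original|ancient
deep	loc_deep	-	deep|lacunar|lacune|basal ganglia|thalamus|thalamic|internal capsule|capsular|pons|pontine|brainstem|centrum semiovale
cortical	loc_cortical	-	cortical|cortex|lobar|frontal|parietal|temporal|occipital|frontal lobe|parietal lobe|temporal lobe|occipital lobe
aneurysmal	mod_aneurysmal	-	aneurysmal|aneurysm
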
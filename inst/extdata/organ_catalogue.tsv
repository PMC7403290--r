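# orgseg organ catalogue v1
# One row per catalogue entry: display name, singular form used when a paired
# organ is expanded to left/right entries, anatomical group, number of
# instances, and the instance class driving the instance-network pathway.
name	singular	group	count	instance_class
Skull	Skull	bone	1	plain
Mandible	Mandible	bone	1	plain
Cervical vertebrae	Cervical vertebrae	bone	7	vertebra
Thoracic vertebrae	Thoracic vertebrae	bone	12	vertebra
Lumbar vertebrae	Lumbar vertebrae	bone	5	vertebra
Ribs	Rib	bone	24	rib
Sacrum and coccyx	Sacrum and coccyx	bone	1	plain
Hip bones	Hip bone	bone	2	plain
Scapulae	Scapula	bone	2	plain
Clavicles	Clavicle	bone	2	plain
Sternum manubrium	Sternum manubrium	bone	1	plain
Sternum body	Sternum body	bone	1	plain
Humerus	Humerus	bone	2	plain
Radius	Radius	bone	2	plain
Ulna	Ulna	bone	2	plain
Hand	Hand	bone	2	plain
Femur	Femur	bone	2	plain
Tibia	Tibia	bone	2	plain
Fibula	Fibula	bone	2	plain
Patella	Patella	bone	2	plain
Foot	Foot	bone	2	plain
Adrenal gland	Adrenal gland	soft_tissue	2	plain
Brain	Brain	soft_tissue	1	plain
Lungs	Lung	soft_tissue	2	plain
Trachea	Trachea	soft_tissue	1	plain
Bronchi	Bronchus	soft_tissue	2	plain
Heart	Heart	soft_tissue	1	plain
Aorta	Aorta	soft_tissue	1	plain
Ventricle	Ventricle	soft_tissue	1	plain
Gastrointestinal tract	Gastrointestinal tract	soft_tissue	1	plain
Liver	Liver	soft_tissue	1	plain
Gallbladder	Gallbladder	soft_tissue	1	plain
Spleen	Spleen	soft_tissue	1	plain
Pancreas	Pancreas	soft_tissue	1	plain
Kidneys	Kidney	soft_tissue	2	plain
Urinary bladder	Urinary bladder	soft_tissue	1	plain
Prostate	Prostate	soft_tissue	1	plain
Testes	Testes	soft_tissue	1	plain
Muscle gluteus maximus	Muscle gluteus maximus	soft_tissue	2	plain
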
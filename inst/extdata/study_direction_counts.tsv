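feature_set	class	split	left	right
head_rot	left	training	48	4
head_rot	centre	training	65	72
head_rot	right	training	9	28
head_rot	left	validation_toddler	4	1
head_rot	centre	validation_toddler	23	27
head_rot	right	validation_toddler	0	1
head_rot	left	validation_infant	13	11
head_rot	centre	validation_infant	102	100
head_rot	right	validation_infant	21	31
gaze_left	left	training	39	4
gaze_left	centre	training	78	84
gaze_left	right	training	5	16
gaze_left	left	validation_toddler	4	0
gaze_left	centre	validation_toddler	23	29
gaze_left	right	validation_toddler	0	0
gaze_left	left	validation_infant	7	2
gaze_left	centre	validation_infant	127	131
gaze_left	right	validation_infant	2	9
gaze_angle	left	training	43	5
gaze_angle	centre	training	67	78
gaze_angle	right	training	12	21
gaze_angle	left	validation_toddler	5	0
gaze_angle	centre	validation_toddler	22	28
gaze_angle	right	validation_toddler	0	1
gaze_angle	left	validation_infant	14	10
gaze_angle	centre	validation_infant	116	114
gaze_angle	right	validation_infant	6	18
pca2	left	training	45	4
pca2	centre	training	72	82
pca2	right	training	5	18
pca2	left	validation_toddler	5	0
pca2	centre	validation_toddler	22	28
pca2	right	validation_toddler	0	1
pca2	left	validation_infant	15	10
pca2	centre	validation_infant	118	122
pca2	right	validation_infant	3	10
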
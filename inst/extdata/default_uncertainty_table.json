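{
  "distances": {
    "femur_left": [0, 0, 0, 0, 0],
    "femur_right": [0, 0, 0, 0, 0],
    "bladder": [3, 3, 0, 0, 0],
    "spine": [3, 3, 0, 6, 6],
    "aorta": [6, 9, 3, 6.70820393249937, 3],
    "humerus_left": [0, 0, 0, 0, 0],
    "humerus_right": [0, 6, 0, 6, 0],
    "kidney_right": [0, 3, 0, 0, 0],
    "kidney_left": [0, 0, 0, 0, 0],
    "liver": [0, 3, 0, 3, 3],
    "spleen": [0, 0, 3, 3, 0],
    "heart": [3, 0, 3, 0, 3],
    "lung_right": [0, 3, 3, 3, 0],
    "lung_left": [0, 0, 3, 0, 3],
    "brain": [0, 3, 3, 0, 0],
    "skull": [0, 3, 6, 0, 3]
  },
  "q75": {
    "femur_left": 0,
    "femur_right": 0,
    "bladder": 3,
    "spine": 6,
    "aorta": 6.70820393249937,
    "humerus_left": 0,
    "humerus_right": 6,
    "kidney_right": 0,
    "kidney_left": 0,
    "liver": 3,
    "spleen": 3,
    "heart": 3,
    "lung_right": 3,
    "lung_left": 3,
    "brain": 3,
    "skull": 3
  }
}
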
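{
  "name": "gaitmuscle generic lower-limb model (synthetic)",
  "version": "1.0",
  "units": "mm",
  "segments": {
    "pelvis": {
      "length_mm": 240,
      "description": "inter-ASIS width"
    },
    "femur": {
      "length_mm": 400,
      "description": "hip to knee center"
    },
    "tibia": {
      "length_mm": 380,
      "description": "knee to ankle center"
    },
    "foot": {
      "length_mm": 150,
      "description": "heel to toe, sagittal"
    }
  },
  "landmarks_pelvis_mm": {
    "P1a": [0, 0, 120],
    "P2a": [20, -90, 0],
    "P4a": [0, 0, -120]
  },
  "hip_center_pelvis_mm": [0, -70, 90],
  "ankle_height_mm": 70,
  "heel_foot_mm": [-50, -70, 0],
  "toe_foot_mm": [100, -70, 0],
  "gait_fourier_deg": {
    "hip": {
      "a0": 10,
      "a": [20, 0, 1],
      "b": [5, 3, 0]
    },
    "knee": {
      "a0": 25,
      "a": [-15, 5, 2],
      "b": [-10, 8, 0]
    },
    "ankle": {
      "a0": 0,
      "a": [-5, 3, 1],
      "b": [-8, 2, 0]
    }
  },
  "muscles": [
    {
      "name": "Glut_Max1",
      "origin": [-120, 20, 40],
      "origin_segment": "pelvis",
      "insertion": [-20, -80, 20],
      "insertion_segment": "femur",
      "pennation_deg": 5,
      "L0_mm": 233.8,
      "fiber_length_cm": 14.2
    },
    {
      "name": "TFL",
      "origin": [10, 0, 120],
      "origin_segment": "pelvis",
      "insertion": [25, -40, 25],
      "insertion_segment": "tibia",
      "pennation_deg": 3,
      "L0_mm": 492,
      "fiber_length_cm": 9.5
    },
    {
      "name": "Iliacus",
      "origin": [30, 20, 30],
      "origin_segment": "pelvis",
      "insertion": [10, -60, -10],
      "insertion_segment": "femur",
      "pennation_deg": 7,
      "L0_mm": 153.9,
      "fiber_length_cm": 10
    },
    {
      "name": "Pectineus",
      "origin": [20, -20, 10],
      "origin_segment": "pelvis",
      "insertion": [-5, -100, 0],
      "insertion_segment": "femur",
      "pennation_deg": 0,
      "L0_mm": 173.2,
      "fiber_length_cm": 13.3
    },
    {
      "name": "Vas_Int",
      "origin": [15, -150, 0],
      "origin_segment": "femur",
      "insertion": [40, 20, 0],
      "insertion_segment": "tibia",
      "pennation_deg": 3,
      "L0_mm": 257.4,
      "fiber_length_cm": 8.7
    },
    {
      "name": "Med_Gas",
      "origin": [-15, -380, -15],
      "origin_segment": "femur",
      "insertion": [-40, -30, 0],
      "insertion_segment": "foot",
      "pennation_deg": 17,
      "L0_mm": 426.8,
      "fiber_length_cm": 4.5
    },
    {
      "name": "Tib_Ant",
      "origin": [15, -100, 10],
      "origin_segment": "tibia",
      "insertion": [60, -20, -20],
      "insertion_segment": "foot",
      "pennation_deg": 5,
      "L0_mm": 315.4,
      "fiber_length_cm": 9.8
    },
    {
      "name": "Tib_Post",
      "origin": [-10, -80, 0],
      "origin_segment": "tibia",
      "insertion": [20, -30, -25],
      "insertion_segment": "foot",
      "pennation_deg": 12,
      "L0_mm": 335.1,
      "fiber_length_cm": 3.1
    },
    {
      "name": "Soleus",
      "origin": [-15, -60, 0],
      "origin_segment": "tibia",
      "insertion": [-40, -30, 0],
      "insertion_segment": "foot",
      "pennation_deg": 25,
      "L0_mm": 358.1,
      "fiber_length_cm": 3
    }
  ]
}
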
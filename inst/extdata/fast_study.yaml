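# Fast study profile: coarse voxels and a small detector so the whole
# pipeline (cohort -> 3D -> DRR -> 2D -> sensitivity -> ICC -> correction)
# runs in a few minutes on one CPU.
"n": 6
seed: 1
fast: true
repeat_poses: 5
correct_poses: 5
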
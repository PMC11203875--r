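# Default pipeline configuration (pipeline_config() fields).
voxel_size_m: 0.05          # background voxel edge, m
n_training_frames: 4        # frames used to fit the background
min_occupancy_frames: 2     # voxel occupancy threshold, frames
link_dist_m: 0.01           # cluster chaining distance, m
min_pts: 20                 # minimum cluster point count
max_pts: 900                # maximum cluster point count
gate_m: 0.09                # track linking gate, m
min_length_frames: 10       # minimum time series length, frames
window_frames: 10           # classifier feature window, frames
max_angle_deg: 110          # turning-angle removal threshold, degrees
fence_k: 1.5                # IQR fence multiplier
frame_rate_fps: 55          # camera frame rate
steps_ahead: 2              # prediction lead, frames
track_from_frame: 4         # first frame handed to the tracker
seed: 0
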
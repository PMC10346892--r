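activity,channel,offset,amplitude,frequency,harmonic_ratio,noise_sd
sitting,waist_accel_x,-0.5,0,0,0,0.1
standing,waist_accel_x,0.1,0,0,0,0.1
walking,waist_accel_x,0.2,1,2,0.3,0.1
ramp_ascent,waist_accel_x,0.6,0.9,1.8,0.3,0.1
ramp_descent,waist_accel_x,-0.4,0.95,1.9,0.3,0.1
stair_ascent,waist_accel_x,0.8,0.8,1.5,0.3,0.1
stair_descent,waist_accel_x,-0.6,0.85,1.6,0.3,0.1
sitting,waist_accel_y,0.3,0,0,0,0.1
standing,waist_accel_y,1,0,0,0,0.1
walking,waist_accel_y,1,0.7,2,0.3,0.1
ramp_ascent,waist_accel_y,1.1,0.63,1.8,0.3,0.1
ramp_descent,waist_accel_y,0.9,0.6649999999999999,1.9,0.3,0.1
stair_ascent,waist_accel_y,1.15,0.5599999999999999,1.5,0.3,0.1
stair_descent,waist_accel_y,0.85,0.595,1.6,0.3,0.1
sitting,waist_gyro_x,0,0,0,0,0.1
standing,waist_gyro_x,0,0,0,0,0.1
walking,waist_gyro_x,0,0.8,2,0.3,0.1
ramp_ascent,waist_gyro_x,0,0.7200000000000001,1.8,0.3,0.1
ramp_descent,waist_gyro_x,0,0.76,1.9,0.3,0.1
stair_ascent,waist_gyro_x,0,0.6400000000000001,1.5,0.3,0.1
stair_descent,waist_gyro_x,0,0.68,1.6,0.3,0.1
sitting,thigh_l_accel_x,0.9,0,0,0,0.1
standing,thigh_l_accel_x,0.1,0,0,0,0.1
walking,thigh_l_accel_x,0.2,1,2,0.3,0.1
ramp_ascent,thigh_l_accel_x,0.5,0.9,1.8,0.3,0.1
ramp_descent,thigh_l_accel_x,-0.3,0.95,1.9,0.3,0.1
stair_ascent,thigh_l_accel_x,0.7,0.8,1.5,0.3,0.1
stair_descent,thigh_l_accel_x,-0.5,0.85,1.6,0.3,0.1
sitting,thigh_l_accel_z,0.3,0,0,0,0.1
standing,thigh_l_accel_z,0.95,0,0,0,0.1
walking,thigh_l_accel_z,0.9,0.6,2,0.3,0.1
ramp_ascent,thigh_l_accel_z,0.85,0.54,1.8,0.3,0.1
ramp_descent,thigh_l_accel_z,0.9,0.57,1.9,0.3,0.1
stair_ascent,thigh_l_accel_z,0.75,0.48,1.5,0.3,0.1
stair_descent,thigh_l_accel_z,0.85,0.51,1.6,0.3,0.1
sitting,thigh_l_gyro_y,0,0,0,0,0.1
standing,thigh_l_gyro_y,0,0,0,0,0.1
walking,thigh_l_gyro_y,0,0.8,2,0.3,0.1
ramp_ascent,thigh_l_gyro_y,0,0.7200000000000001,1.8,0.3,0.1
ramp_descent,thigh_l_gyro_y,0,0.76,1.9,0.3,0.1
stair_ascent,thigh_l_gyro_y,0,0.6400000000000001,1.5,0.3,0.1
stair_descent,thigh_l_gyro_y,0,0.68,1.6,0.3,0.1
sitting,thigh_r_accel_x,0.9,0,0,0,0.1
standing,thigh_r_accel_x,0.1,0,0,0,0.1
walking,thigh_r_accel_x,0.2,1,2,0.3,0.1
ramp_ascent,thigh_r_accel_x,0.5,0.9,1.8,0.3,0.1
ramp_descent,thigh_r_accel_x,-0.3,0.95,1.9,0.3,0.1
stair_ascent,thigh_r_accel_x,0.7,0.8,1.5,0.3,0.1
stair_descent,thigh_r_accel_x,-0.5,0.85,1.6,0.3,0.1
sitting,thigh_r_accel_z,0.3,0,0,0,0.1
standing,thigh_r_accel_z,0.95,0,0,0,0.1
walking,thigh_r_accel_z,0.9,0.6,2,0.3,0.1
ramp_ascent,thigh_r_accel_z,0.85,0.54,1.8,0.3,0.1
ramp_descent,thigh_r_accel_z,0.9,0.57,1.9,0.3,0.1
stair_ascent,thigh_r_accel_z,0.75,0.48,1.5,0.3,0.1
stair_descent,thigh_r_accel_z,0.85,0.51,1.6,0.3,0.1
sitting,thigh_r_gyro_y,0,0,0,0,0.1
standing,thigh_r_gyro_y,0,0,0,0,0.1
walking,thigh_r_gyro_y,0,0.8,2,0.3,0.1
ramp_ascent,thigh_r_gyro_y,0,0.7200000000000001,1.8,0.3,0.1
ramp_descent,thigh_r_gyro_y,0,0.76,1.9,0.3,0.1
stair_ascent,thigh_r_gyro_y,0,0.6400000000000001,1.5,0.3,0.1
stair_descent,thigh_r_gyro_y,0,0.68,1.6,0.3,0.1
sitting,shank_l_accel_x,0.1,0,0,0,0.1
standing,shank_l_accel_x,0.05,0,0,0,0.1
walking,shank_l_accel_x,0.15,1,2,0.3,0.1
ramp_ascent,shank_l_accel_x,0.45,0.9,1.8,0.3,0.1
ramp_descent,shank_l_accel_x,-0.25,0.95,1.9,0.3,0.1
stair_ascent,shank_l_accel_x,0.6,0.8,1.5,0.3,0.1
stair_descent,shank_l_accel_x,-0.4,0.85,1.6,0.3,0.1
sitting,shank_l_accel_z,0.95,0,0,0,0.1
standing,shank_l_accel_z,0.95,0,0,0,0.1
walking,shank_l_accel_z,0.9,0.6,2,0.3,0.1
ramp_ascent,shank_l_accel_z,0.85,0.54,1.8,0.3,0.1
ramp_descent,shank_l_accel_z,0.9,0.57,1.9,0.3,0.1
stair_ascent,shank_l_accel_z,0.8,0.48,1.5,0.3,0.1
stair_descent,shank_l_accel_z,0.85,0.51,1.6,0.3,0.1
sitting,shank_l_gyro_y,0,0,0,0,0.1
standing,shank_l_gyro_y,0,0,0,0,0.1
walking,shank_l_gyro_y,0,0.8,2,0.3,0.1
ramp_ascent,shank_l_gyro_y,0,0.7200000000000001,1.8,0.3,0.1
ramp_descent,shank_l_gyro_y,0,0.76,1.9,0.3,0.1
stair_ascent,shank_l_gyro_y,0,0.6400000000000001,1.5,0.3,0.1
stair_descent,shank_l_gyro_y,0,0.68,1.6,0.3,0.1
sitting,shank_r_accel_x,0.1,0,0,0,0.1
standing,shank_r_accel_x,0.05,0,0,0,0.1
walking,shank_r_accel_x,0.15,1,2,0.3,0.1
ramp_ascent,shank_r_accel_x,0.45,0.9,1.8,0.3,0.1
ramp_descent,shank_r_accel_x,-0.25,0.95,1.9,0.3,0.1
stair_ascent,shank_r_accel_x,0.6,0.8,1.5,0.3,0.1
stair_descent,shank_r_accel_x,-0.4,0.85,1.6,0.3,0.1
sitting,shank_r_accel_z,0.95,0,0,0,0.1
standing,shank_r_accel_z,0.95,0,0,0,0.1
walking,shank_r_accel_z,0.9,0.6,2,0.3,0.1
ramp_ascent,shank_r_accel_z,0.85,0.54,1.8,0.3,0.1
ramp_descent,shank_r_accel_z,0.9,0.57,1.9,0.3,0.1
stair_ascent,shank_r_accel_z,0.8,0.48,1.5,0.3,0.1
stair_descent,shank_r_accel_z,0.85,0.51,1.6,0.3,0.1
sitting,shank_r_gyro_y,0,0,0,0,0.1
standing,shank_r_gyro_y,0,0,0,0,0.1
walking,shank_r_gyro_y,0,0.8,2,0.3,0.1
ramp_ascent,shank_r_gyro_y,0,0.7200000000000001,1.8,0.3,0.1
ramp_descent,shank_r_gyro_y,0,0.76,1.9,0.3,0.1
stair_ascent,shank_r_gyro_y,0,0.6400000000000001,1.5,0.3,0.1
stair_descent,shank_r_gyro_y,0,0.68,1.6,0.3,0.1
sitting,knee_l_angle,1.5,0,0,0,0.05
standing,knee_l_angle,0.1,0,0,0,0.05
walking,knee_l_angle,0.6,0.6,2,0.3,0.05
ramp_ascent,knee_l_angle,0.7,0.54,1.85,0.3,0.05
ramp_descent,knee_l_angle,0.7,0.54,1.85,0.3,0.05
stair_ascent,knee_l_angle,1,0.66,1.55,0.3,0.05
stair_descent,knee_l_angle,1,0.66,1.55,0.3,0.05
sitting,knee_r_angle,1.5,0,0,0,0.05
standing,knee_r_angle,0.1,0,0,0,0.05
walking,knee_r_angle,0.6,0.6,2,0.3,0.05
ramp_ascent,knee_r_angle,0.7,0.54,1.85,0.3,0.05
ramp_descent,knee_r_angle,0.7,0.54,1.85,0.3,0.05
stair_ascent,knee_r_angle,1,0.66,1.55,0.3,0.05
stair_descent,knee_r_angle,1,0.66,1.55,0.3,0.05
sitting,ankle_l_angle,0.2,0,0,0,0.05
standing,ankle_l_angle,0.1,0,0,0,0.05
walking,ankle_l_angle,0.3,0.4,2,0.3,0.05
ramp_ascent,ankle_l_angle,0.45,0.36000000000000004,1.85,0.3,0.05
ramp_descent,ankle_l_angle,0.45,0.36000000000000004,1.85,0.3,0.05
stair_ascent,ankle_l_angle,0.35,0.44000000000000006,1.55,0.3,0.05
stair_descent,ankle_l_angle,0.35,0.44000000000000006,1.55,0.3,0.05
sitting,ankle_r_angle,0.2,0,0,0,0.05
standing,ankle_r_angle,0.1,0,0,0,0.05
walking,ankle_r_angle,0.3,0.4,2,0.3,0.05
ramp_ascent,ankle_r_angle,0.45,0.36000000000000004,1.85,0.3,0.05
ramp_descent,ankle_r_angle,0.45,0.36000000000000004,1.85,0.3,0.05
stair_ascent,ankle_r_angle,0.35,0.44000000000000006,1.55,0.3,0.05
stair_descent,ankle_r_angle,0.35,0.44000000000000006,1.55,0.3,0.05
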
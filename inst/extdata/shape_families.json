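{
  "bathtub": {"family": "open_tub", "parts": ["bottom_slab", "side_wall", "side_wall", "end_wall", "end_wall"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "bear": {"family": "two_sphere_quadruped", "parts": ["body_sphere", "head_sphere", "leg_cylinder x4"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "bird": {"family": "winged_ellipsoid", "parts": ["body_ellipsoid", "head_sphere", "beak_cone", "tail_plate"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "butterfly": {"family": "paired_wing_plates", "parts": ["body_cylinder", "wing_plate x2"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "elephant": {"family": "box_quadruped_trunk", "parts": ["body_box", "leg_cylinder x4", "trunk_cylinder"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "fish": {"family": "finned_ellipsoid", "parts": ["body_ellipsoid", "tail_cone"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "helmet": {"family": "dome_with_brim", "parts": ["dome_ellipsoid", "brim_cylinder"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "mailbox": {"family": "vaulted_box_on_post", "parts": ["body_box", "roof_half_cylinder", "post_cylinder"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "mug": {"family": "cylinder_with_handle", "parts": ["cup_cylinder", "handle_torus"], "front_axis": [1, 0, 0], "jitter": 0.15},
  "phone": {"family": "thin_slab", "parts": ["body_slab", "camera_bump"], "front_axis": [1, 0, 0], "jitter": 0.15}
}
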
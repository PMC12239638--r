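# Default trait definitions: 21 linear and centroid-size traits across the
# three body planes (body, small cross-section, large cross-section).
# Landmark indices are 0-based. distance = straight-line distance between two
# landmarks; mean_distance = average of several such distances (bilateral or
# paired measures averaged prior to analysis); centroid_size = centroid size
# of a landmark subset ("all" = every landmark on the plane).
# The eye diameter is the mean of the horizontal (2:3) and vertical (4:5)
# bony-orbit distances. Override by supplying your own file to
# read_trait_definitions().
traits:
  - {name: dorsal_fin, plane: body, type: distance, landmarks: [12, 13]}
  - {name: anal_fin, plane: body, type: distance, landmarks: [16, 17]}
  - {name: pectoral_fin, plane: body, type: distance, landmarks: [10, 11]}
  - {name: tail_fin, plane: body, type: distance, landmarks: [19, 20]}
  - {name: caudal_peduncle, plane: body, type: distance, landmarks: [15, 18]}
  - {name: eye_diameter, plane: body, type: mean_distance,
     pairs: [[2, 3], [4, 5]]}
  - {name: snout_length, plane: body, type: distance, landmarks: [1, 0]}
  - {name: eye_vertical_position, plane: body, type: distance, landmarks: [0, 6]}
  - {name: head_length, plane: body, type: distance, landmarks: [1, 7]}
  - {name: head_width, plane: body, type: distance, landmarks: [8, 9]}
  - {name: body_centroid_size, plane: body, type: centroid_size, landmarks: all}
  - {name: head_centroid_size, plane: body, type: centroid_size,
     landmarks: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9]}
  - {name: vertebra_thickness_sml, plane: small_xsec, type: distance, landmarks: [3, 4]}
  - {name: xsec_diameter_sml, plane: small_xsec, type: distance, landmarks: [5, 7]}
  - {name: aerobic_muscle_sml, plane: small_xsec, type: mean_distance,
     pairs: [[7, 8], [5, 6]]}
  - {name: centroid_size_sml, plane: small_xsec, type: centroid_size, landmarks: all}
  - {name: vertebra_thickness_lrg, plane: large_xsec, type: distance, landmarks: [6, 7]}
  - {name: xsec_diameter_lrg, plane: large_xsec, type: distance, landmarks: [12, 8]}
  - {name: aerobic_muscle_lrg, plane: large_xsec, type: mean_distance,
     pairs: [[8, 9], [12, 13]]}
  - {name: aerobic_muscle_vert_lrg, plane: large_xsec, type: mean_distance,
     pairs: [[14, 15], [10, 11]]}
  - {name: centroid_size_lrg, plane: large_xsec, type: centroid_size, landmarks: all}
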
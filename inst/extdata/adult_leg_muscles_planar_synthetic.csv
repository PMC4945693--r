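# Planar (sagittal) reduction of an adult lower-limb muscle set: 18 muscles
# with straight-line or single-via paths.  Path points are given per segment
# as a fraction of the segment's reference length along its long axis plus a
# perpendicular offset in mm (positive = anterior with the thigh vertical).
# fmax_N are adult maximum isometric forces approximating published gait
# model values.  This table is a synthetic digitization constructed for the
# planar model (3D wrapping surfaces and broad attachment sites are reduced
# to fixed via points); swap this file to use a different source dataset.
# Segments: pelvis (reference length 100 mm), femur (396), tibia (430),
# foot (150).  group = joint whose surrounding musculature the muscle is
# reported under (hip or knee).
name,group,fmax_N,p1_seg,p1_frac,p1_perp,p2_seg,p2_frac,p2_perp,p3_seg,p3_frac,p3_perp
psoas,hip,1113,pelvis,-0.30,40,femur,0.15,10,,,
iliacus,hip,1073,pelvis,-0.15,42,femur,0.13,10,,,
rectus_femoris,hip,1169,pelvis,-0.05,30,femur,0.95,45,tibia,0.08,35
gluteus_medius,hip,2045,pelvis,-0.30,-10,femur,0.03,-15,,,
adductor_magnus,hip,2268,pelvis,0.05,-20,femur,0.45,-5,,,
biceps_femoris,hip,896,pelvis,0.00,-35,femur,0.97,-22,tibia,0.08,-30
gluteus_maximus,hip,1944,pelvis,-0.25,-45,femur,0.25,-15,,,
piriformis,hip,444,pelvis,-0.30,-30,femur,0.02,-10,,,
gemelli,hip,164,pelvis,-0.15,-25,femur,0.02,-12,,,
sartorius,hip,156,pelvis,-0.10,50,femur,0.97,-10,tibia,0.10,-8
semitendinosus,hip,410,pelvis,0.00,-35,femur,0.97,-20,tibia,0.12,-25
gracilis,knee,137,pelvis,0.05,-15,femur,0.97,-15,tibia,0.12,-18
soleus,knee,3549,tibia,0.30,-20,foot,-0.33,-10,,,
tibialis_posterior,knee,2900,tibia,0.40,-15,foot,-0.05,-16,foot,0.25,-8
tibialis_anterior,knee,905,tibia,0.30,20,foot,0.08,26,foot,0.35,8
gastrocnemius_medialis,knee,1558,femur,0.92,-25,femur,1.00,-22,foot,-0.33,-10
vastus_intermedius,knee,1365,femur,0.30,25,femur,0.95,45,tibia,0.08,35
vastus_lateralis,knee,1871,femur,0.30,28,femur,0.95,45,tibia,0.08,35
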
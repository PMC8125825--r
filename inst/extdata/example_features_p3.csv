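participant_id,activity,repetition,true_category,hr,fwr_active,fwr_mean,most_active_hand
P3,Brushing one's hair,1,unimanual,32.11,NA,NA,unknown
P3,Brushing one's hair,2,unimanual,54.26,NA,NA,unknown
P3,Brushing one's hair,3,unimanual,66.41,NA,NA,unknown
P3,Brushing one's hair,4,unimanual,68.41,NA,NA,unknown
P3,Brushing one's hair,5,unimanual,83.61,NA,NA,unknown
P3,Using a spoon,1,unimanual,56.73,NA,NA,unknown
P3,Using a spoon,2,unimanual,32.44,NA,NA,unknown
P3,Using a spoon,3,unimanual,41.81,NA,NA,unknown
P3,Using a spoon,4,unimanual,67.44,NA,NA,unknown
P3,Using a spoon,5,unimanual,59.21,NA,NA,unknown
P3,Drinking a cup of water,1,unimanual,48.90,NA,NA,unknown
P3,Drinking a cup of water,2,unimanual,58.22,NA,NA,unknown
P3,Drinking a cup of water,3,unimanual,68.75,NA,NA,unknown
P3,Drinking a cup of water,4,unimanual,68.21,NA,NA,unknown
P3,Drinking a cup of water,5,unimanual,85.08,NA,NA,unknown
P3,Writing a sentence,1,bimanual_stab_finger,27.72,2.80,NA,unknown
P3,Writing a sentence,2,bimanual_stab_finger,25.11,2.72,NA,unknown
P3,Writing a sentence,3,bimanual_stab_finger,26.97,2.80,NA,unknown
P3,Writing a sentence,4,bimanual_stab_finger,20.13,2.83,NA,unknown
P3,Writing a sentence,5,bimanual_stab_finger,29.52,2.68,NA,unknown
P3,Spreading butter on a slice of bread,1,bimanual_stab_global,7.63,1.72,NA,unknown
P3,Spreading butter on a slice of bread,2,bimanual_stab_global,8.10,1.62,NA,unknown
P3,Spreading butter on a slice of bread,3,bimanual_stab_global,11.44,1.61,NA,unknown
P3,Spreading butter on a slice of bread,4,bimanual_stab_global,10.69,1.61,NA,unknown
P3,Spreading butter on a slice of bread,5,bimanual_stab_global,16.35,1.49,NA,unknown
P3,Opening a can with a can opener,1,bimanual_stab_global,5.92,2.29,NA,unknown
P3,Opening a can with a can opener,2,bimanual_stab_global,8.52,2.67,NA,unknown
P3,Opening a can with a can opener,3,bimanual_stab_global,9.98,2.01,NA,unknown
P3,Opening a can with a can opener,4,bimanual_stab_global,11.93,2.10,NA,unknown
P3,Opening a can with a can opener,5,bimanual_stab_global,11.41,2.10,NA,unknown
P3,Typing on a computer keyboard,1,bimanual_both_finger,3.21,NA,5.77,unknown
P3,Typing on a computer keyboard,2,bimanual_both_finger,2.50,NA,5.58,unknown
P3,Typing on a computer keyboard,3,bimanual_both_finger,2.75,NA,5.20,unknown
P3,Typing on a computer keyboard,4,bimanual_both_finger,3.11,NA,5.29,unknown
P3,Typing on a computer keyboard,5,bimanual_both_finger,2.91,NA,5.36,unknown
P3,Shuffling and dealing cards,1,bimanual_both_finger,2.80,NA,2.97,unknown
P3,Shuffling and dealing cards,2,bimanual_both_finger,2.44,NA,3.28,unknown
P3,Shuffling and dealing cards,3,bimanual_both_finger,2.58,NA,2.93,unknown
P3,Shuffling and dealing cards,4,bimanual_both_finger,2.59,NA,3.23,unknown
P3,Shuffling and dealing cards,5,bimanual_both_finger,2.58,NA,3.24,unknown
P3,Peeling potatoes with a knife,1,bimanual_both_finger,1.74,NA,2.80,unknown
P3,Peeling potatoes with a knife,2,bimanual_both_finger,1.97,NA,2.62,unknown
P3,Peeling potatoes with a knife,3,bimanual_both_finger,1.93,NA,2.90,unknown
P3,Peeling potatoes with a knife,4,bimanual_both_finger,1.98,NA,3.07,unknown
P3,Peeling potatoes with a knife,5,bimanual_both_finger,1.94,NA,3.02,unknown
P3,Buttoning a shirt,1,bimanual_both_finger,2.20,NA,3.00,unknown
P3,Buttoning a shirt,2,bimanual_both_finger,2.01,NA,3.13,unknown
P3,Buttoning a shirt,3,bimanual_both_finger,2.42,NA,2.88,unknown
P3,Buttoning a shirt,4,bimanual_both_finger,2.16,NA,3.27,unknown
P3,Buttoning a shirt,5,bimanual_both_finger,2.67,NA,3.16,unknown
P3,Tying shoelaces,1,bimanual_both_finger,2.71,NA,2.75,unknown
P3,Tying shoelaces,2,bimanual_both_finger,4.27,NA,2.64,unknown
P3,Tying shoelaces,3,bimanual_both_finger,2.42,NA,2.85,unknown
P3,Tying shoelaces,4,bimanual_both_finger,3.16,NA,2.60,unknown
P3,Tying shoelaces,5,bimanual_both_finger,2.61,NA,2.54,unknown
P3,Opening a screw-topped jar,1,bimanual_both_global,1.93,NA,2.02,unknown
P3,Opening a screw-topped jar,2,bimanual_both_global,1.77,NA,1.98,unknown
P3,Opening a screw-topped jar,3,bimanual_both_global,1.78,NA,2.18,unknown
P3,Opening a screw-topped jar,4,bimanual_both_global,2.15,NA,1.94,unknown
P3,Opening a screw-topped jar,5,bimanual_both_global,1.92,NA,2.43,unknown
P3,Lifting a full pan,1,bimanual_both_global,1.51,NA,1.70,unknown
P3,Lifting a full pan,2,bimanual_both_global,1.52,NA,1.55,unknown
P3,Lifting a full pan,3,bimanual_both_global,1.54,NA,1.56,unknown
P3,Lifting a full pan,4,bimanual_both_global,1.50,NA,1.50,unknown
P3,Lifting a full pan,5,bimanual_both_global,1.51,NA,1.49,unknown
P3,Wringing a towel,1,bimanual_both_global,2.29,NA,2.01,unknown
P3,Wringing a towel,2,bimanual_both_global,2.17,NA,1.72,unknown
P3,Wringing a towel,3,bimanual_both_global,2.15,NA,2.19,unknown
P3,Wringing a towel,4,bimanual_both_global,2.54,NA,1.87,unknown
P3,Wringing a towel,5,bimanual_both_global,2.38,NA,1.73,unknown
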
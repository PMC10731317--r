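breed,registry,eye_colour_recommendation
synthetic_breed_01,AKC,dark
synthetic_breed_02,AKC,dark
synthetic_breed_03,AKC,dark
synthetic_breed_04,AKC,dark
synthetic_breed_05,AKC,dark
synthetic_breed_06,AKC,dark
synthetic_breed_07,AKC,dark
synthetic_breed_08,AKC,dark
synthetic_breed_09,AKC,dark
synthetic_breed_10,AKC,dark
synthetic_breed_11,AKC,dark
synthetic_breed_12,AKC,dark
synthetic_breed_13,AKC,dark
synthetic_breed_14,AKC,dark
synthetic_breed_15,AKC,dark
synthetic_breed_16,AKC,dark
synthetic_breed_17,AKC,dark
synthetic_breed_18,AKC,dark
synthetic_breed_19,AKC,dark
synthetic_breed_20,AKC,dark
synthetic_breed_21,AKC,dark
synthetic_breed_22,AKC,dark
synthetic_breed_23,AKC,dark
synthetic_breed_24,AKC,dark
synthetic_breed_25,AKC,dark
synthetic_breed_26,AKC,dark
synthetic_breed_27,AKC,dark
synthetic_breed_28,AKC,dark
synthetic_breed_29,AKC,dark
synthetic_breed_30,AKC,dark
synthetic_breed_31,AKC,dark
synthetic_breed_32,AKC,dark
synthetic_breed_33,AKC,dark
synthetic_breed_34,AKC,dark
synthetic_breed_35,AKC,dark
synthetic_breed_36,AKC,dark
synthetic_breed_37,AKC,dark
synthetic_breed_38,AKC,dark
synthetic_breed_39,AKC,dark
synthetic_breed_40,AKC,dark
synthetic_breed_41,AKC,dark
synthetic_breed_42,AKC,dark
synthetic_breed_43,AKC,dark
synthetic_breed_44,AKC,dark
synthetic_breed_45,AKC,dark
synthetic_breed_46,AKC,dark
synthetic_breed_47,AKC,dark
synthetic_breed_48,AKC,dark
synthetic_breed_49,AKC,dark
synthetic_breed_50,AKC,dark
synthetic_breed_51,AKC,dark
synthetic_breed_52,AKC,dark
synthetic_breed_53,AKC,dark
synthetic_breed_54,AKC,dark
synthetic_breed_55,AKC,dark
synthetic_breed_56,AKC,dark
synthetic_breed_57,AKC,dark
synthetic_breed_58,AKC,dark
synthetic_breed_59,AKC,dark
synthetic_breed_60,AKC,dark
synthetic_breed_61,AKC,dark
synthetic_breed_62,AKC,dark
synthetic_breed_63,AKC,dark
synthetic_breed_64,AKC,dark
synthetic_breed_65,AKC,dark
synthetic_breed_66,AKC,dark
synthetic_breed_67,AKC,dark
synthetic_breed_68,AKC,dark
synthetic_breed_69,AKC,dark
synthetic_breed_70,AKC,dark
synthetic_breed_71,AKC,dark
synthetic_breed_72,AKC,dark
synthetic_breed_73,AKC,dark
synthetic_breed_74,AKC,dark
synthetic_breed_75,AKC,dark
synthetic_breed_76,AKC,dark
synthetic_breed_77,AKC,dark
synthetic_breed_78,AKC,other
synthetic_breed_79,AKC,other
synthetic_breed_80,AKC,other
synthetic_breed_81,AKC,other
synthetic_breed_82,AKC,other
synthetic_breed_01,KC,dark
synthetic_breed_02,KC,dark
synthetic_breed_03,KC,dark
synthetic_breed_04,KC,dark
synthetic_breed_05,KC,dark
synthetic_breed_06,KC,dark
synthetic_breed_07,KC,dark
synthetic_breed_08,KC,dark
synthetic_breed_09,KC,dark
synthetic_breed_10,KC,dark
synthetic_breed_11,KC,dark
synthetic_breed_12,KC,dark
synthetic_breed_13,KC,dark
synthetic_breed_14,KC,dark
synthetic_breed_15,KC,dark
synthetic_breed_16,KC,dark
synthetic_breed_17,KC,dark
synthetic_breed_18,KC,dark
synthetic_breed_19,KC,dark
synthetic_breed_20,KC,dark
synthetic_breed_21,KC,dark
synthetic_breed_22,KC,dark
synthetic_breed_23,KC,dark
synthetic_breed_24,KC,dark
synthetic_breed_25,KC,dark
synthetic_breed_26,KC,dark
synthetic_breed_27,KC,dark
synthetic_breed_28,KC,dark
synthetic_breed_29,KC,dark
synthetic_breed_30,KC,dark
synthetic_breed_31,KC,dark
synthetic_breed_32,KC,dark
synthetic_breed_33,KC,dark
synthetic_breed_34,KC,dark
synthetic_breed_35,KC,dark
synthetic_breed_36,KC,dark
synthetic_breed_37,KC,dark
synthetic_breed_38,KC,dark
synthetic_breed_39,KC,dark
synthetic_breed_40,KC,dark
synthetic_breed_41,KC,dark
synthetic_breed_42,KC,dark
synthetic_breed_43,KC,dark
synthetic_breed_44,KC,dark
synthetic_breed_45,KC,dark
synthetic_breed_46,KC,dark
synthetic_breed_47,KC,dark
synthetic_breed_48,KC,dark
synthetic_breed_49,KC,dark
synthetic_breed_50,KC,dark
synthetic_breed_51,KC,dark
synthetic_breed_52,KC,dark
synthetic_breed_53,KC,dark
synthetic_breed_54,KC,dark
synthetic_breed_55,KC,dark
synthetic_breed_56,KC,dark
synthetic_breed_57,KC,dark
synthetic_breed_58,KC,dark
synthetic_breed_59,KC,dark
synthetic_breed_60,KC,dark
synthetic_breed_61,KC,dark
synthetic_breed_62,KC,dark
synthetic_breed_63,KC,dark
synthetic_breed_64,KC,dark
synthetic_breed_65,KC,dark
synthetic_breed_66,KC,dark
synthetic_breed_67,KC,dark
synthetic_breed_68,KC,dark
synthetic_breed_69,KC,dark
synthetic_breed_70,KC,dark
synthetic_breed_71,KC,dark
synthetic_breed_72,KC,dark
synthetic_breed_73,KC,dark
synthetic_breed_74,KC,dark
synthetic_breed_75,KC,dark
synthetic_breed_76,KC,dark
synthetic_breed_77,KC,other
synthetic_breed_78,KC,other
synthetic_breed_79,KC,other
synthetic_breed_80,KC,other
synthetic_breed_81,KC,other
synthetic_breed_82,KC,other
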
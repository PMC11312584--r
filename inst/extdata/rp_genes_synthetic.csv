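gene_id,protein_id,copy_class,paralog_partner
RPL3,eL3,single,
RPL5,eL5,single,
RPL10,eL10,single,
RPL25,eL25,single,
RPL28,eL28,single,
RPL29,eL29,single,
RPL30,eL30,single,
RPL32,eL32,single,
RPL38,eL38,single,
RPL39,eL39,single,
RPS2,eS2,single,
RPS3,eS3,single,
RPS5,eS5,single,
RPS13,eS13,single,
RPS15,eS15,single,
RPS20,eS20,single,
RPS31,eS31,single,
RPP0,P0,single,
ASC1,RACK1,single,
RPL1A,eL1,duplicated,RPL1B
RPL1B,eL1,duplicated,RPL1A
RPL2A,eL2,duplicated,RPL2B
RPL2B,eL2,duplicated,RPL2A
RPL4A,eL4,duplicated,RPL4B
RPL4B,eL4,duplicated,RPL4A
RPL6A,eL6,duplicated,RPL6B
RPL6B,eL6,duplicated,RPL6A
RPL7A,eL7,duplicated,RPL7B
RPL7B,eL7,duplicated,RPL7A
RPL8A,eL8,duplicated,RPL8B
RPL8B,eL8,duplicated,RPL8A
RPL9A,eL9,duplicated,RPL9B
RPL9B,eL9,duplicated,RPL9A
RPL11A,eL11,duplicated,RPL11B
RPL11B,eL11,duplicated,RPL11A
RPL12A,eL12,duplicated,RPL12B
RPL12B,eL12,duplicated,RPL12A
RPL13A,eL13,duplicated,RPL13B
RPL13B,eL13,duplicated,RPL13A
RPL14A,eL14,duplicated,RPL14B
RPL14B,eL14,duplicated,RPL14A
RPL15A,eL15,duplicated,RPL15B
RPL15B,eL15,duplicated,RPL15A
RPL16A,eL16,duplicated,RPL16B
RPL16B,eL16,duplicated,RPL16A
RPL17A,eL17,duplicated,RPL17B
RPL17B,eL17,duplicated,RPL17A
RPL18A,eL18,duplicated,RPL18B
RPL18B,eL18,duplicated,RPL18A
RPL19A,eL19,duplicated,RPL19B
RPL19B,eL19,duplicated,RPL19A
RPL20A,eL20,duplicated,RPL20B
RPL20B,eL20,duplicated,RPL20A
RPL21A,eL21,duplicated,RPL21B
RPL21B,eL21,duplicated,RPL21A
RPL22A,eL22,duplicated,RPL22B
RPL22B,eL22,duplicated,RPL22A
RPL23A,eL23,duplicated,RPL23B
RPL23B,eL23,duplicated,RPL23A
RPL24A,eL24,duplicated,RPL24B
RPL24B,eL24,duplicated,RPL24A
RPL26A,eL26,duplicated,RPL26B
RPL26B,eL26,duplicated,RPL26A
RPL27A,eL27,duplicated,RPL27B
RPL27B,eL27,duplicated,RPL27A
RPL31A,eL31,duplicated,RPL31B
RPL31B,eL31,duplicated,RPL31A
RPL33A,eL33,duplicated,RPL33B
RPL33B,eL33,duplicated,RPL33A
RPL34A,eL34,duplicated,RPL34B
RPL34B,eL34,duplicated,RPL34A
RPL35A,eL35,duplicated,RPL35B
RPL35B,eL35,duplicated,RPL35A
RPL36A,eL36,duplicated,RPL36B
RPL36B,eL36,duplicated,RPL36A
RPL37A,eL37,duplicated,RPL37B
RPL37B,eL37,duplicated,RPL37A
RPL40A,eL40,duplicated,RPL40B
RPL40B,eL40,duplicated,RPL40A
RPL41A,eL41,duplicated,RPL41B
RPL41B,eL41,duplicated,RPL41A
RPL42A,eL42,duplicated,RPL42B
RPL42B,eL42,duplicated,RPL42A
RPL43A,eL43,duplicated,RPL43B
RPL43B,eL43,duplicated,RPL43A
RPS0A,eS0,duplicated,RPS0B
RPS0B,eS0,duplicated,RPS0A
RPS1A,eS1,duplicated,RPS1B
RPS1B,eS1,duplicated,RPS1A
RPS4A,eS4,duplicated,RPS4B
RPS4B,eS4,duplicated,RPS4A
RPS6A,eS6,duplicated,RPS6B
RPS6B,eS6,duplicated,RPS6A
RPS7A,eS7,duplicated,RPS7B
RPS7B,eS7,duplicated,RPS7A
RPS8A,eS8,duplicated,RPS8B
RPS8B,eS8,duplicated,RPS8A
RPS9A,eS9,duplicated,RPS9B
RPS9B,eS9,duplicated,RPS9A
RPS10A,eS10,duplicated,RPS10B
RPS10B,eS10,duplicated,RPS10A
RPS11A,eS11,duplicated,RPS11B
RPS11B,eS11,duplicated,RPS11A
RPS12A,eS12,duplicated,RPS12B
RPS12B,eS12,duplicated,RPS12A
RPS14A,eS14,duplicated,RPS14B
RPS14B,eS14,duplicated,RPS14A
RPS16A,eS16,duplicated,RPS16B
RPS16B,eS16,duplicated,RPS16A
RPS17A,eS17,duplicated,RPS17B
RPS17B,eS17,duplicated,RPS17A
RPS18A,eS18,duplicated,RPS18B
RPS18B,eS18,duplicated,RPS18A
RPS19A,eS19,duplicated,RPS19B
RPS19B,eS19,duplicated,RPS19A
RPS21A,eS21,duplicated,RPS21B
RPS21B,eS21,duplicated,RPS21A
RPS22A,eS22,duplicated,RPS22B
RPS22B,eS22,duplicated,RPS22A
RPS23A,eS23,duplicated,RPS23B
RPS23B,eS23,duplicated,RPS23A
RPS24A,eS24,duplicated,RPS24B
RPS24B,eS24,duplicated,RPS24A
RPS25A,eS25,duplicated,RPS25B
RPS25B,eS25,duplicated,RPS25A
RPS26A,eS26,duplicated,RPS26B
RPS26B,eS26,duplicated,RPS26A
RPS27A,eS27,duplicated,RPS27B
RPS27B,eS27,duplicated,RPS27A
RPS28A,eS28,duplicated,RPS28B
RPS28B,eS28,duplicated,RPS28A
RPS29A,eS29,duplicated,RPS29B
RPS29B,eS29,duplicated,RPS29A
RPS30A,eS30,duplicated,RPS30B
RPS30B,eS30,duplicated,RPS30A
RPP1A,P1,duplicated,RPP1B
RPP1B,P1,duplicated,RPP1A
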